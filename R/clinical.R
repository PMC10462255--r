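#' Classify best overall response from percent tumor-size change
#'
#' RECIST-style thresholds on the best percent change from baseline of the
#' target-lesion sum: `-100` is complete response (CR), `<= -30` partial
#' response (PR), `>= +20` progressive disease (PD), anything between stable
#' disease (SD). Boundaries are inclusive, so exactly `-30` is PR and exactly
#' `+20` is PD.
#'
#' @param pct_change Numeric vector of percent changes; values below `-100`
#'   are impossible and raise an error.
#' @return Ordered factor with levels `CR < PR < SD < PD`.
#' @examples
#' classify_bor(c(-100, -30, 0, 20))
#' @export
classify_bor <- function(pct_change) {
  if (any(pct_change < -100, na.rm = TRUE)) {
    stop("percent change below -100 is impossible", call. = FALSE)
  }
  out <- dplyr::case_when(
    pct_change == -100 ~ "CR",
    pct_change <= -30 ~ "PR",
    pct_change >= 20 ~ "PD",
    TRUE ~ "SD"
  )
  factor(out, levels = c("CR", "PR", "SD", "PD"), ordered = TRUE)
}

# percentages to one decimal, half away from zero (printed trial style)
round_pct <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarize a trial response table
#'
#' Rates are computed over evaluable subjects only and reported as
#' percentages to one decimal (rounding half away from zero): the confirmed
#' objective response rate under RECIST and under irRECIST, the clinical
#' benefit rate (benefit strictly beyond `benefit_cutoff_months`), and the
#' fraction not starting a new therapy within one year.
#'
#' @param rows Data frame of subject responses (see
#'   [read_response_table()] for the columns).
#' @param benefit_cutoff_months Strict benefit cutoff (default 6 months).
#' @return A one-row tibble: `n_evaluable`, `n_recist`, `orr_recist_pct`,
#'   `n_irrecist`, `orr_irrecist_pct`, `n_benefit`, `cbr_pct`,
#'   `n_no_new_therapy_1yr`, `no_new_therapy_1yr_pct`.
#' @export
summarize_trial <- function(rows, benefit_cutoff_months = 6) {
  ev <- rows[rows$evaluable, , drop = FALSE]
  n <- nrow(ev)
  if (n == 0L) stop("no evaluable subject", call. = FALSE)
  n_rec <- sum(ev$confirmed_recist)
  n_irr <- sum(ev$confirmed_irrecist)
  benefit <- ev$benefit_months > benefit_cutoff_months
  n_ben <- sum(benefit)
  n_nont <- sum(!ev$new_therapy_within_1yr)
  tibble::tibble(
    n_evaluable = n,
    n_recist = n_rec, orr_recist_pct = round_pct(100 * n_rec / n),
    n_irrecist = n_irr, orr_irrecist_pct = round_pct(100 * n_irr / n),
    n_benefit = n_ben, cbr_pct = round_pct(100 * n_ben / n),
    n_no_new_therapy_1yr = n_nont,
    no_new_therapy_1yr_pct = round_pct(100 * n_nont / n)
  )
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Right-censored product-limit estimator: at each distinct event time the
#' survival probability is multiplied by `1 - d/n` (events over number at
#' risk); censored times reduce the risk set without a step.
#'
#' @param records Data frame with columns `time` (nonnegative) and `event`
#'   (logical or 0/1; `TRUE` = event observed, `FALSE` = right-censored).
#' @return A tibble, one row per distinct observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (the estimate just after `time`).
#' @export
kaplan_meier <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) stop("need at least 1 record", call. = FALSE)
  if (any(records$time < 0)) stop("negative survival time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = transform(records,
                                            event = as.integer(event)))
  sm <- summary(fit, censored = TRUE)
  tibble::tibble(time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
                 n_censor = sm$n.censor, survival = sm$surv)
}

#' Waterfall table of best overall responses
#'
#' Prepares the per-subject plotting table behind a waterfall chart:
#' evaluable subjects sorted by best percent change, largest (worst) first,
#' with the best-overall-response category and a clinical-benefit flag
#' attached. Ties in percent change keep the `subject_id` order stable.
#'
#' @param rows Data frame of subject responses.
#' @param benefit_cutoff_months Strict benefit cutoff (default 6 months).
#' @return A tibble with `subject_id`, `best_pct_change`, `bor`,
#'   `clinical_benefit`, sorted for plotting.
#' @export
waterfall_table <- function(rows, benefit_cutoff_months = 6) {
  ev <- tibble::as_tibble(rows[rows$evaluable, , drop = FALSE])
  if (nrow(ev) == 0L) {
    return(tibble::tibble(subject_id = character(),
                          best_pct_change = double(),
                          bor = factor(character(),
                                       levels = c("CR", "PR", "SD", "PD"),
                                       ordered = TRUE),
                          clinical_benefit = logical()))
  }
  ev |>
    dplyr::mutate(bor = classify_bor(.data$best_pct_change),
                  clinical_benefit =
                    .data$benefit_months > benefit_cutoff_months) |>
    dplyr::arrange(dplyr::desc(.data$best_pct_change), .data$subject_id) |>
    dplyr::select("subject_id", "best_pct_change", "bor", "clinical_benefit")
}
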
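#' Per-cell direction-aware pathway score
#'
#' A cell's score for a pathway is the mean over the pathway's target genes
#' present in the cohort of the signed expression `s_g * x_g`, where
#' `s_g = +1` for targets expected up under activation and `-1` for targets
#' expected down.
#'
#' @param cohort A [cell_cohort()].
#' @param pw A [pathway_definition()].
#' @param signed Use direction weights (default `TRUE`, the single-cell
#'   convention).
#' @return A tibble with the cell annotations plus `pathway` and `score`.
#' @export
pathway_score_cells <- function(cohort, pw, signed = TRUE) {
  stopifnot(inherits(cohort, "cell_cohort"), inherits(pw, "pathway_def"))
  s <- target_signs(pw)
  present <- intersect(names(s), colnames(cohort$values))
  if (length(present) == 0L) {
    stop("no target of pathway '", pw$regulator, "' found in the cohort",
         call. = FALSE)
  }
  w <- if (signed) s[present] else rep(1, length(present))
  score <- as.vector(cohort$values[, present, drop = FALSE] %*% w) /
    length(present)
  dplyr::mutate(cohort$cells, pathway = pw$regulator, score = score)
}

#' Apply the malignant-cell / total-cell tumor filters
#'
#' Tumors are retained when they have at least `min_malignant` malignant
#' cells and at least `min_total` cells in total (both bounds inclusive);
#' excluded tumors are reported in a message.
#'
#' @param cohort A [cell_cohort()].
#' @param min_malignant,min_total Inclusive lower bounds (defaults 40 / 100).
#' @return A tibble `tumor_name`, `n_malignant`, `n_total`, `kept`.
#' @export
filter_tumors <- function(cohort, min_malignant = 40L, min_total = 100L) {
  tab <- cohort$cells |>
    dplyr::group_by(.data$tumor_name) |>
    dplyr::summarise(n_malignant = sum(.data$is_malignant),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(kept = .data$n_malignant >= min_malignant &
                    .data$n_total >= min_total)
  dropped <- tab$tumor_name[!tab$kept]
  if (length(dropped)) {
    message("excluding ", length(dropped), " tumor(s) failing the ",
            min_malignant, "/", min_total, " cell filters: ",
            paste(dropped, collapse = ", "))
  }
  if (all(!tab$kept)) warning("no tumor passes the cell filters",
                              call. = FALSE)
  tab
}

#' Per-tumor T cell fraction
#'
#' Fraction of all sequenced cells of a tumor annotated as T cells.
#'
#' @param cohort A [cell_cohort()].
#' @param tcell_labels Cell-type tokens counted as T cells (published
#'   annotations differ; configure to match yours).
#' @return A tibble `tumor_name`, `n_cells`, `n_tcells`, `fraction`.
#' @export
tcell_fraction <- function(cohort,
                           tcell_labels = c("T cell", "Tcell", "T")) {
  if (!any(cohort$cells$cell_type %in% tcell_labels)) {
    warning("no cell matches the T cell labels (",
            paste(tcell_labels, collapse = ", "), "); all fractions are 0",
            call. = FALSE)
  }
  cohort$cells |>
    dplyr::group_by(.data$tumor_name) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_tcells = sum(.data$cell_type %in% tcell_labels),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_tcells / .data$n_cells)
}

#' Assign tumors to low / high T cell infiltration groups
#'
#' Default is a quantile (median) split on the T cell fraction: tumors at or
#' below the split quantile are `low`, the rest `high`. The `"extreme"` mode
#' instead keeps only the bottom-`k` (`low`) and top-`k` (`high`) tumors and
#' marks the remainder `excluded`.
#'
#' @param fractions Tibble from [tcell_fraction()] (needs `tumor_name`,
#'   `fraction`) or a named numeric vector of fractions.
#' @param split Quantile for the split mode (default 0.5, the median).
#' @param mode `"quantile"` or `"extreme"`.
#' @param k Group size for the extreme mode.
#' @return A tibble `tumor_name`, `fraction`, `group` (`low` / `high` /
#'   `excluded`).
#' @export
assign_infiltration_groups <- function(fractions, split = 0.5,
                                       mode = c("quantile", "extreme"),
                                       k = 1L) {
  mode <- match.arg(mode)
  if (is.numeric(fractions)) {
    fractions <- tibble::tibble(tumor_name = names(fractions),
                                fraction = unname(fractions))
  }
  fractions <- tibble::as_tibble(fractions)
  if (nrow(fractions) < 2L) stop("need at least 2 tumors", call. = FALSE)
  fr <- fractions$fraction
  if (diff(range(fr)) == 0) {
    stop("all T cell fractions equal; supply an explicit assignment",
         call. = FALSE)
  }
  if (mode == "quantile") {
    cut <- stats::quantile(fr, split, names = FALSE)
    grp <- ifelse(fr <= cut, "low", "high")
  } else {
    ord <- order(fr, fractions$tumor_name)
    grp <- rep("excluded", length(fr))
    grp[ord[seq_len(k)]] <- "low"
    grp[rev(ord)[seq_len(k)]] <- "high"
  }
  dplyr::mutate(fractions[, c("tumor_name", "fraction")], group = grp)
}

#' Mixed-model contrast of per-cell scores between infiltration groups
#'
#' Fits, by maximum likelihood, the linear mixed model
#' `score ~ 0 + group + (1 | tumor)` (group fixed effect, patient/tumor
#' random intercept) and the null model without the group effect, and tests
#' the group effect with a 1-df likelihood ratio chi-square. The estimate is
#' the fitted low-group mean minus the high-group mean. When the mixed fit is
#' singular (zero between-tumor variance) the contrast falls back to an OLS
#' fit with a maximum-likelihood LRT, flagged in the result.
#'
#' @param data Data frame with one row per cell.
#' @param score,group,tumor Column names (strings) of the per-cell score, the
#'   `"low"`/`"high"` group label, and the tumor/patient id.
#' @return An object of class `infiltration_contrast` with elements
#'   `estimate` (low minus high), `p` (LRT), `method` (`"lmm"` or `"ols"`),
#'   `singular_fallback`, `n_cells`, `n_tumors`, and the fitted models.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
compare_groups_lmm <- function(data, score = "score", group = "group",
                               tumor = "tumor_name") {
  df <- data.frame(score = data[[score]],
                   group = factor(data[[group]], levels = c("low", "high")),
                   tumor = as.character(data[[tumor]]))
  if (anyNA(df$group)) {
    stop("group labels must be 'low' or 'high'", call. = FALSE)
  }
  mix <- unique(df[, c("group", "tumor")])
  if (anyDuplicated(mix$tumor)) {
    stop("each tumor's cells must share one group label", call. = FALSE)
  }
  n_per <- table(mix$group)
  if (any(n_per < 2L)) {
    stop("need at least 2 tumors per group", call. = FALSE)
  }
  fit <- suppressMessages(lme4::lmer(score ~ 0 + group + (1 | tumor),
                                     data = df, REML = FALSE))
  singular <- lme4::isSingular(fit)
  if (!singular) {
    null <- suppressMessages(lme4::lmer(score ~ 1 + (1 | tumor),
                                        data = df, REML = FALSE))
    est <- unname(lme4::fixef(fit)["grouplow"] - lme4::fixef(fit)["grouphigh"])
    method <- "lmm"
  } else {
    fit <- stats::lm(score ~ 0 + group, data = df)
    null <- stats::lm(score ~ 1, data = df)
    est <- unname(stats::coef(fit)["grouplow"] - stats::coef(fit)["grouphigh"])
    method <- "ols"
  }
  stat <- 2 * (as.numeric(stats::logLik(fit)) - as.numeric(stats::logLik(null)))
  p <- stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  structure(
    list(estimate = est, p = p, method = method,
         singular_fallback = singular, lrt_stat = stat,
         n_cells = nrow(df), n_tumors = length(unique(df$tumor)),
         fit = fit, null_fit = null),
    class = "infiltration_contrast"
  )
}

#' @export
print.infiltration_contrast <- function(x, ...) {
  cat("<infiltration_contrast> low - high = ", signif(x$estimate, 4),
      ", LRT p = ", signif(x$p, 3), " (", x$method,
      if (x$singular_fallback) ", singular fallback" else "", "; ",
      x$n_cells, " cells, ", x$n_tumors, " tumors)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.infiltration_contrast <- function(x, ...) {
  tibble::tibble(term = "group_low_vs_high", estimate = x$estimate,
                 statistic = x$lrt_stat, p.value = x$p)
}

#' @export
glance.infiltration_contrast <- function(x, ...) {
  tibble::tibble(method = x$method, singular_fallback = x$singular_fallback,
                 logLik = as.numeric(stats::logLik(x$fit)),
                 n_cells = x$n_cells, n_tumors = x$n_tumors)
}

#' Contrast every pathway between infiltration groups with BH-FDR
#'
#' Scores each pathway per cell (malignant cells only by default, in tumors
#' assigned to a group), runs the mixed-model group contrast, and adjusts the
#' LRT p-values with Benjamini-Hochberg across the pathway family. A pathway
#' is significant when its adjusted p (q) is below `fdr_threshold` (default
#' 0.10). Per-pathway failures are reported in the `error` column; the FDR is
#' computed over the successful fits.
#'
#' @param cohort A [cell_cohort()].
#' @param pathways List of [pathway_definition()] objects.
#' @param assignment Tibble from [assign_infiltration_groups()].
#' @param malignant_only Restrict scoring to malignant cells (default `TRUE`).
#' @param signed Direction-aware per-cell scores (default `TRUE`).
#' @param fdr_threshold Significance threshold on q (default 0.10).
#' @return A tibble `pathway`, `estimate`, `p`, `q`, `significant`,
#'   `singular_fallback`, `error`, in input order.
#' @export
compare_groups_all <- function(cohort, pathways, assignment,
                               malignant_only = TRUE, signed = TRUE,
                               fdr_threshold = 0.10) {
  if (length(pathways) == 0L) {
    return(tibble::tibble(pathway = character(), estimate = double(),
                          p = double(), q = double(), significant = logical(),
                          singular_fallback = logical(), error = character()))
  }
  grouped <- assignment[assignment$group %in% c("low", "high"), ]
  if (length(unique(grouped$group)) < 2L) {
    stop("assignment must contain both low and high tumors", call. = FALSE)
  }
  sub <- subset_cells(cohort, tumors = grouped$tumor_name)
  if (malignant_only) sub <- subset_cells(sub, cells = sub$cells$is_malignant)
  res <- purrr::map_dfr(pathways, function(pw) {
    out <- tryCatch({
      sc <- pathway_score_cells(sub, pw, signed = signed)
      sc$group <- grouped$group[match(sc$tumor_name, grouped$tumor_name)]
      ct <- compare_groups_lmm(sc)
      tibble::tibble(pathway = pw$regulator, estimate = ct$estimate,
                     p = ct$p, singular_fallback = ct$singular_fallback,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(pathway = pw$regulator, estimate = NA_real_,
                     p = NA_real_, singular_fallback = NA,
                     error = conditionMessage(e))
    })
    out
  })
  if (any(!is.na(res$error))) {
    warning(sum(!is.na(res$error)), " pathway(s) failed; FDR computed over ",
            "the successful fits", call. = FALSE)
  }
  res$q <- NA_real_
  ok <- is.na(res$error)
  res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$q) & res$q < fdr_threshold
  res[, c("pathway", "estimate", "p", "q", "significant",
          "singular_fallback", "error")]
}

#' Nested mixed-model contrast of scores between two cell types
#'
#' Tests whether one cell population (e.g. malignant epithelial cells)
#' expresses a pathway more strongly than another (e.g. fibroblasts) while
#' accounting for patient structure: a maximum-likelihood fit of
#' `score ~ 0 + cell_type + (1 | tumor/cell_type)` (random intercepts for
#' tumor and for cell type within tumor) against the null without the fixed
#' cell-type effect, with a 1-df LRT.
#'
#' @param data Data frame with one row per cell, restricted internally to the
#'   two cell types.
#' @param type_a,type_b The two `cell_type` labels; the estimate is the
#'   fitted `type_a` mean minus the `type_b` mean.
#' @param score,cell_type,tumor Column names.
#' @return An `infiltration_contrast` object (estimate = A minus B).
#' @export
compare_celltypes_nested <- function(data, type_a, type_b, score = "score",
                                     cell_type = "cell_type",
                                     tumor = "tumor_name") {
  df <- data.frame(score = data[[score]],
                   cell_type = as.character(data[[cell_type]]),
                   tumor = as.character(data[[tumor]]))
  df <- df[df$cell_type %in% c(type_a, type_b), ]
  for (ty in c(type_a, type_b)) {
    n_tum <- length(unique(df$tumor[df$cell_type == ty]))
    if (n_tum == 0L) stop("cell type '", ty, "' absent", call. = FALSE)
    if (n_tum < 2L) {
      stop("cell type '", ty, "' present in fewer than 2 tumors",
           call. = FALSE)
    }
  }
  df$cell_type <- factor(df$cell_type, levels = c(type_a, type_b))
  fit <- suppressMessages(lme4::lmer(
    score ~ 0 + cell_type + (1 | tumor / cell_type), data = df, REML = FALSE))
  singular <- lme4::isSingular(fit)
  if (!singular) {
    null <- suppressMessages(lme4::lmer(
      score ~ 1 + (1 | tumor / cell_type), data = df, REML = FALSE))
    cf <- lme4::fixef(fit)
    est <- unname(cf[paste0("cell_type", type_a)] -
                    cf[paste0("cell_type", type_b)])
    method <- "lmm"
  } else {
    fit <- stats::lm(score ~ 0 + cell_type, data = df)
    null <- stats::lm(score ~ 1, data = df)
    cf <- stats::coef(fit)
    est <- unname(cf[paste0("cell_type", type_a)] -
                    cf[paste0("cell_type", type_b)])
    method <- "ols"
  }
  stat <- 2 * (as.numeric(stats::logLik(fit)) - as.numeric(stats::logLik(null)))
  p <- stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  structure(
    list(estimate = est, p = p, method = method, singular_fallback = singular,
         lrt_stat = stat, n_cells = nrow(df),
         n_tumors = length(unique(df$tumor)), fit = fit, null_fit = null),
    class = "infiltration_contrast"
  )
}

#' Per-tumor pseudobulk of a cell cohort
#'
#' Mean expression per tumor over a chosen cell subset (malignant cells by
#' default), the aggregation used for per-tumor pathway activation scoring.
#'
#' @param cohort A [cell_cohort()].
#' @param cells `"malignant"` or `"all"`.
#' @return Tumors x genes numeric matrix.
#' @export
pseudobulk <- function(cohort, cells = c("malignant", "all")) {
  cells <- match.arg(cells)
  if (cells == "malignant") {
    cohort <- subset_cells(cohort, cells = cohort$cells$is_malignant)
  }
  vals <- as.matrix(cohort$values)
  tumors <- sort(unique(cohort$cells$tumor_name))
  out <- t(vapply(tumors, function(tn) {
    colMeans(vals[cohort$cells$tumor_name == tn, , drop = FALSE])
  }, numeric(ncol(vals))))
  rownames(out) <- tumors
  out
}

#' Per-tumor p38 activation score
#'
#' Each signature gene is centered and scaled to unit variance across tumors;
#' a tumor's activation score is the mean of these standardized values over
#' the signature genes present. By construction the cohort mean of the scores
#' is zero. Zero-variance genes carry no contrast and are dropped with a
#' warning; if every gene is dropped the score is undefined and an error is
#' raised.
#'
#' @param tumor_expr Tumors x genes matrix: bulk expression or a malignant
#'   cell [pseudobulk()]. Needs >= 2 tumors.
#' @param sig A [gene_signature()]; defaults to the packaged
#'   [p38_signature()].
#' @return A tibble `tumor_name`, `score`.
#' @export
p38_score_tumors <- function(tumor_expr, sig = p38_signature()) {
  stopifnot(is.matrix(tumor_expr))
  if (nrow(tumor_expr) < 2L) stop("need at least 2 tumors", call. = FALSE)
  present <- intersect(sig$genes, colnames(tumor_expr))
  if (length(present) == 0L) {
    stop("no gene of signature '", sig$name, "' found in the matrix",
         call. = FALSE)
  }
  sub <- tumor_expr[, present, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s) from '",
            sig$name, "'", call. = FALSE)
    sub <- sub[, sds > 0, drop = FALSE]
  }
  if (ncol(sub) == 0L) {
    stop("all signature genes have zero variance; score undefined",
         call. = FALSE)
  }
  z <- scale(sub)
  tibble::tibble(tumor_name = rownames(tumor_expr),
                 score = rowMeans(z))
}
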
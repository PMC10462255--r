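#' Score samples on a gene signature
#'
#' The T cell-inflamed score of a sample is the unweighted mean of its
#' normalized, log-transformed expression over the signature genes present in
#' the matrix. Missing signature genes are reported with a message; zero
#' overlap is an error.
#'
#' @param expr Samples x genes numeric matrix (normalized log expression).
#' @param sig A [gene_signature()].
#' @return A tibble with columns `sample_id`, `score`.
#' @export
tci_score <- function(expr, sig) {
  stopifnot(is.matrix(expr), inherits(sig, "gene_signature"))
  present <- intersect(sig$genes, colnames(expr))
  if (length(present) == 0L) {
    stop("no gene of signature '", sig$name, "' found in the matrix",
         call. = FALSE)
  }
  missing <- setdiff(sig$genes, present)
  if (length(missing)) {
    message(length(missing), " gene(s) of signature '", sig$name,
            "' absent from the matrix")
  }
  tibble::tibble(sample_id = rownames(expr),
                 score = unname(rowMeans(expr[, present, drop = FALSE])))
}

#' Classify tumors into inflammation phenotypes by score quantiles
#'
#' Samples at or below the `lower_q` quantile of the score are called
#' `non_inflamed`, samples at or above the `upper_q` quantile `inflamed`, and
#' the rest `intermediate` (default: tertiles). If all scores are equal the
#' split is undefined and every sample is `intermediate`, with a warning.
#'
#' @param scores Tibble from [tci_score()] (columns `sample_id`, `score`) or
#'   a named numeric vector.
#' @param lower_q,upper_q Quantile bounds in (0, 1), `lower_q < upper_q`.
#' @return A tibble `sample_id`, `score`, `phenotype` (factor with levels
#'   `non_inflamed`, `intermediate`, `inflamed`).
#' @export
classify_tci <- function(scores, lower_q = 1 / 3, upper_q = 2 / 3) {
  scores <- as_score_tbl(scores)
  stopifnot(lower_q > 0, upper_q < 1, lower_q < upper_q)
  if (nrow(scores) < 3L) stop("need at least 3 samples", call. = FALSE)
  lv <- c("non_inflamed", "intermediate", "inflamed")
  x <- scores$score
  if (diff(range(x)) == 0) {
    warning("all scores equal; classifying every sample as intermediate",
            call. = FALSE)
    klass <- rep("intermediate", length(x))
  } else {
    qs <- stats::quantile(x, c(lower_q, upper_q), names = FALSE)
    klass <- dplyr::case_when(x <= qs[1] ~ "non_inflamed",
                              x >= qs[2] ~ "inflamed",
                              TRUE ~ "intermediate")
  }
  dplyr::mutate(scores, phenotype = factor(klass, levels = lv))
}

as_score_tbl <- function(scores) {
  if (is.numeric(scores)) {
    ids <- names(scores)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_along(scores))
    return(tibble::tibble(sample_id = ids, score = unname(scores)))
  }
  tibble::as_tibble(scores)
}

#' Per-sample pathway activation score in bulk data
#'
#' The pathway score of a sample is the mean expression of the pathway's
#' target genes. In signed mode each target enters with weight `+1` (expected
#' up) or `-1` (expected down); the default for bulk data is the plain
#' (unsigned) mean of all targets.
#'
#' @param expr Samples x genes numeric matrix.
#' @param pw A [pathway_definition()].
#' @param signed Use direction-aware signed weights (default `FALSE` for
#'   bulk; per-cell scoring defaults to signed, see [pathway_score_cells()]).
#' @return A tibble `sample_id`, `pathway`, `score`.
#' @export
pathway_score_bulk <- function(expr, pw, signed = FALSE) {
  stopifnot(is.matrix(expr), inherits(pw, "pathway_def"))
  s <- target_signs(pw)
  present <- intersect(names(s), colnames(expr))
  if (length(present) == 0L) {
    stop("no target of pathway '", pw$regulator, "' found in the matrix",
         call. = FALSE)
  }
  w <- if (signed) s[present] else rep(1, length(present))
  score <- as.vector(expr[, present, drop = FALSE] %*% w) / length(present)
  tibble::tibble(sample_id = rownames(expr), pathway = pw$regulator,
                 score = score)
}

#' Concordance activation z-score for a pathway between two sample classes
#'
#' For each present target gene the class-mean log difference
#' `d_g = mean_A(x_g) - mean_B(x_g)` is compared with the expected direction
#' `s_g` (+1 up / -1 down); the activation z-score is the net concordance
#' `z = sum_g sign(d_g) * s_g / sqrt(N)` over the `N` present targets, so a
#' pathway whose targets all move as expected in class A reaches `sqrt(N)`.
#' The p-value is a two-sided Welch t-test on the per-sample signed pathway
#' score between the classes, and the pathway is called activated when
#' `z >= z_threshold` and `p < p_threshold` (defaults 1.95 and 0.05).
#'
#' @param expr Samples x genes numeric matrix.
#' @param pw A [pathway_definition()].
#' @param samples_a,samples_b Character vectors of sample ids for the two
#'   classes (e.g. non-inflamed vs inflamed); each needs >= 2 samples.
#' @param z_threshold,p_threshold Activation-call thresholds.
#' @return A one-row tibble: `pathway`, `n_targets`, `zscore`, `p`,
#'   `activated`.
#' @export
activation_zscore <- function(expr, pw, samples_a, samples_b,
                              z_threshold = 1.95, p_threshold = 0.05) {
  stopifnot(is.matrix(expr), inherits(pw, "pathway_def"))
  samples_a <- intersect(samples_a, rownames(expr))
  samples_b <- intersect(samples_b, rownames(expr))
  if (length(samples_a) < 2L || length(samples_b) < 2L) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  s <- target_signs(pw)
  present <- intersect(names(s), colnames(expr))
  if (length(present) == 0L) {
    stop("no target of pathway '", pw$regulator, "' found in the matrix",
         call. = FALSE)
  }
  d <- colMeans(expr[samples_a, present, drop = FALSE]) -
    colMeans(expr[samples_b, present, drop = FALSE])
  z <- sum(sign(d) * s[present]) / sqrt(length(present))
  sc <- pathway_score_bulk(expr, pw, signed = TRUE)
  sa <- sc$score[match(samples_a, sc$sample_id)]
  sb <- sc$score[match(samples_b, sc$sample_id)]
  p <- tryCatch(stats::t.test(sa, sb)$p.value, error = function(e) NA_real_)
  tibble::tibble(pathway = pw$regulator, n_targets = length(present),
                 zscore = z, p = p,
                 activated = !is.na(p) && z >= z_threshold && p < p_threshold)
}

#' Regress co-occurring pathway activation on inflammation score
#'
#' Ordinary least squares of the per-sample number of co-occurring activated
#' pathways (or any per-sample pathway burden) on the T cell-inflamed score,
#' quantifying the inverse relationship between inflammation and pathway
#' activation.
#'
#' @param data Data frame with the two variables, or `NULL` when vectors are
#'   given directly.
#' @param tci,n_activated Column names (tidy-select style strings) when
#'   `data` is supplied, otherwise numeric vectors of equal length >= 3.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p` (slope
#'   t-test p-value).
#' @export
cooccurrence_regression <- function(data = NULL, tci = "tci",
                                    n_activated = "n_activated") {
  if (is.data.frame(data)) {
    x <- data[[tci]]
    y <- data[[n_activated]]
  } else {
    x <- tci
    y <- n_activated
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in the inflammation score",
                               call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = unname(sm$coefficients[2, 4]))
}

#' Correlate pathway scores with the T cell-inflamed score
#'
#' Continuous validation: the per-sample signature score is correlated with
#' each pathway's per-sample score. A pathway whose score vector is constant
#' has no defined correlation; it yields `NA` with a warning and does not
#' affect the others.
#'
#' @param expr Samples x genes numeric matrix.
#' @param pathways List of [pathway_definition()] objects.
#' @param sig A [gene_signature()].
#' @param method `"pearson"` or `"spearman"`.
#' @param signed Signed pathway scores (default `FALSE`, as for bulk scores).
#' @return A tibble `pathway`, `r`, `p`, ordered as the input list.
#' @export
correlate_pathways_with_tci <- function(expr, pathways, sig,
                                        method = c("pearson", "spearman"),
                                        signed = FALSE) {
  method <- match.arg(method)
  if (nrow(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  tci <- tci_score(expr, sig)$score
  purrr::map_dfr(pathways, function(pw) {
    ps <- pathway_score_bulk(expr, pw, signed = signed)$score
    if (stats::sd(ps) == 0 || stats::sd(tci) == 0) {
      warning("constant score vector for pathway '", pw$regulator,
              "'; correlation undefined", call. = FALSE)
      return(tibble::tibble(pathway = pw$regulator, r = NA_real_,
                            p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(tci, ps, method = method,
                                           exact = FALSE))
    tibble::tibble(pathway = pw$regulator, r = unname(ct$estimate),
                   p = ct$p.value)
  })
}

#' Per-sample pathway activation call against the cohort median
#'
#' A target is "upregulated" in a sample when its direction-adjusted value
#' `s_g * x_gs` strictly exceeds the direction-adjusted cohort median of that
#' gene; a sample's pathway is called active when at least 50% of the present
#' targets are upregulated (the inclusive >= 50% rule).
#'
#' @param expr Samples x genes numeric matrix with >= 2 samples.
#' @param pw A [pathway_definition()].
#' @param min_frac Fraction of upregulated targets required (inclusive).
#' @return A tibble `sample_id`, `frac_up`, `active`.
#' @export
pathway_activation_call <- function(expr, pw, min_frac = 0.5) {
  stopifnot(is.matrix(expr), inherits(pw, "pathway_def"))
  if (nrow(expr) < 2L) {
    stop("activation calls need a cohort of at least 2 samples", call. = FALSE)
  }
  s <- target_signs(pw)
  present <- intersect(names(s), colnames(expr))
  if (length(present) == 0L) {
    stop("no target of pathway '", pw$regulator, "' found in the matrix",
         call. = FALSE)
  }
  adj <- sweep(expr[, present, drop = FALSE], 2, s[present], `*`)
  med <- apply(adj, 2, stats::median)
  up <- sweep(adj, 2, med, `>`)
  frac <- unname(rowMeans(up))
  tibble::tibble(sample_id = rownames(expr), frac_up = frac,
                 active = frac >= min_frac)
}
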
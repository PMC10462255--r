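#' Relative rank of pathway-level values
#'
#' Maps values onto `(0, 1]`: the pathway best placed according to `best`
#' gets rank `1/N`, the worst gets `1`; ties are averaged.
#'
#' @param values Numeric vector (optionally named by pathway).
#' @param best `"high"` if larger values are better (e.g. activation
#'   z-scores) or `"low"` if smaller values are better (e.g. p-values or
#'   negative correlation coefficients).
#' @return Numeric vector of relative ranks in `(0, 1]`, names preserved.
#' @export
relative_rank <- function(values, best = c("high", "low")) {
  best <- match.arg(best)
  if (length(values) == 0L) stop("no values to rank", call. = FALSE)
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values))
    lab <- if (!is.null(names(values))) names(values)[bad] else bad
    stop("non-finite value(s) for: ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  r <- if (best == "high") rank(-values, ties.method = "average") else
    rank(values, ties.method = "average")
  r / length(values)
}

#' Geometric mean of three relative ranks
#'
#' @param r1,r2,r3 Numeric vectors of ranks in `(0, 1]` (recycled
#'   element-wise).
#' @return `(r1 * r2 * r3)^(1/3)`; always between the componentwise min and
#'   max.
#' @export
combined_rank <- function(r1, r2, r3) {
  if (any(c(r1, r2, r3) <= 0)) {
    stop("ranks must be positive", call. = FALSE)
  }
  (r1 * r2 * r3)^(1 / 3)
}

#' Integrate three evidence streams into a combined pathway priority
#'
#' Combines, per pathway, (1) the bulk activation z-score (higher is better),
#' (2) the continuous anti-correlation with the T cell-inflamed signature
#' (more negative is better), and (3) the single-cell low-vs-high
#' infiltration contrast (smaller p better; or larger effect better with
#' `sc_rank = "effect"`). Each stream is converted to a relative rank, the
#' combined rank is their geometric mean, and a pathway passes when
#' `combined < combined_lt` and the maximum pairwise absolute difference
#' among its three ranks is `< maxdiff_lt` (strict inequalities, defaults
#' 0.6 and 0.3).
#'
#' @param bulk_z,anticorrelation,sc Two-column data frames
#'   (`pathway`, `value`) or named numeric vectors: activation z-scores,
#'   correlation coefficients, and single-cell contrast p-values (or effect
#'   sizes).
#' @param combined_lt,maxdiff_lt Strict pass thresholds.
#' @param sc_rank `"p"` (rank p-values small to large, the default) or
#'   `"effect"` (rank effect sizes large to small).
#' @param impute_missing If `TRUE`, a pathway absent from a stream gets that
#'   stream's worst rank (1) instead of raising an error.
#' @return A tibble sorted by `combined` (ascending, pathway name tiebreak):
#'   `pathway`, `rank_bulk`, `rank_anticor`, `rank_sc`, `combined`,
#'   `max_diff`, `passes`.
#' @export
prioritize <- function(bulk_z, anticorrelation, sc,
                       combined_lt = 0.6, maxdiff_lt = 0.3,
                       sc_rank = c("p", "effect"), impute_missing = FALSE) {
  sc_rank <- match.arg(sc_rank)
  bulk_z <- as_stream(bulk_z)
  anticorrelation <- as_stream(anticorrelation)
  sc <- as_stream(sc)
  all_pw <- union(union(names(bulk_z), names(anticorrelation)), names(sc))
  common <- intersect(intersect(names(bulk_z), names(anticorrelation)),
                      names(sc))
  if (length(common) == 0L) {
    stop("the three streams share no pathway", call. = FALSE)
  }
  if (!impute_missing && length(common) < length(all_pw)) {
    stop("pathway set mismatch across streams: ",
         paste(setdiff(all_pw, common), collapse = ", "),
         " (set impute_missing = TRUE to assign worst rank)", call. = FALSE)
  }
  rank_of <- function(v, best) {
    r <- relative_rank(v, best)
    out <- stats::setNames(rep(1, length(all_pw)), all_pw)
    out[names(r)] <- r
    out
  }
  r1 <- rank_of(bulk_z, "high")
  r2 <- rank_of(anticorrelation, "low")
  r3 <- rank_of(sc, if (sc_rank == "p") "low" else "high")
  comb <- combined_rank(r1, r2, r3)
  md <- pmax(abs(r1 - r2), abs(r1 - r3), abs(r2 - r3))
  out <- tibble::tibble(pathway = all_pw, rank_bulk = unname(r1),
                        rank_anticor = unname(r2), rank_sc = unname(r3),
                        combined = unname(comb), max_diff = unname(md),
                        passes = unname(comb < combined_lt &
                                          md < maxdiff_lt))
  dplyr::arrange(out, .data$combined, .data$pathway)
}

as_stream <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("stream vectors must be named by pathway",
                                call. = FALSE)
    return(x)
  }
  x <- tibble::as_tibble(x)
  if (!all(c("pathway", "value") %in% names(x))) {
    # accept any two-column frame: first column pathway, second value
    if (ncol(x) < 2L) stop("stream needs pathway and value columns",
                           call. = FALSE)
    names(x)[1:2] <- c("pathway", "value")
  }
  stats::setNames(x$value, x$pathway)
}
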
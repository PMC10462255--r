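#' Waterfall plot of best overall response
#'
#' @param wf Tibble from [waterfall_table()].
#' @return A ggplot object: one bar per subject, colored by clinical benefit,
#'   with dashed guides at +20% (PD) and -30% (PR).
#' @export
plot_waterfall <- function(wf) {
  wf <- dplyr::mutate(wf, subject_id = factor(.data$subject_id,
                                              levels = .data$subject_id))
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$subject_id,
                                   y = .data$best_pct_change,
                                   fill = .data$clinical_benefit)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(20, -30), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "Best % change from baseline",
                  fill = "Clinical benefit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Kaplan-Meier step plot
#'
#' @param km Tibble from [kaplan_meier()].
#' @return A ggplot step function of survival over time with censor ticks.
#' @export
plot_km <- function(km) {
  steps <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1), km)
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(km, .data$n_censor > 0),
                        shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Dot plot of combined pathway priorities
#'
#' @param pr Tibble from [prioritize()].
#' @param combined_lt,maxdiff_lt Thresholds drawn as guides (defaults match
#'   [prioritize()]).
#' @return A ggplot of combined relative rank per pathway, pass status
#'   highlighted.
#' @export
plot_priority <- function(pr, combined_lt = 0.6, maxdiff_lt = 0.3) {
  pr <- dplyr::mutate(pr, pathway = factor(.data$pathway,
                                           levels = rev(.data$pathway)))
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$combined, y = .data$pathway,
                                   colour = .data$passes,
                                   size = .data$max_diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = combined_lt, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_size_continuous(range = c(3, 1)) +
    ggplot2::labs(x = "Combined relative rank", y = NULL,
                  colour = sprintf("combined < %.1f & max diff < %.1f",
                                   combined_lt, maxdiff_lt),
                  size = "Max rank difference") +
    ggplot2::theme_minimal()
}

#' Box plot of per-cell pathway scores by infiltration group
#'
#' @param scores Tibble from [pathway_score_cells()] with a `group` column
#'   attached (low/high).
#' @return A ggplot of per-tumor score distributions split by group.
#' @export
plot_group_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$tumor_name,
                                       y = .data$score,
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "Per-cell pathway score",
                  fill = "T cell infiltration") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
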
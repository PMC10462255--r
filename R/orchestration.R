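#' Build a run configuration
#'
#' Collects every tunable threshold of the pipeline in one place, with the
#' published defaults: activation z >= 1.95 with p < 0.05, FDR 0.10 for the
#' single-cell family, combined relative rank < 0.6 with maximum rank
#' difference < 0.3, the >= 40 malignant / >= 100 total cell filters, and the
#' 6-month clinical benefit cutoff. Values from a YAML file are applied on
#' top of the defaults, and `...` overrides on top of those; all overrides
#' are recorded in the output manifests.
#'
#' @param yaml_path Optional YAML file of settings.
#' @param ... Named overrides (e.g. `seed = 7`, `fdr_threshold = 0.05`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(yaml_path = NULL, ...) {
  cfg <- list(
    z_threshold = 1.95, p_threshold = 0.05, fdr_threshold = 0.10,
    combined_lt = 0.6, maxdiff_lt = 0.3,
    min_malignant = 40L, min_total = 100L,
    benefit_cutoff_months = 6,
    signed_bulk = FALSE, signed_sc = TRUE, malignant_only = TRUE,
    split = 0.5, sc_rank = "p",
    tcell_labels = c("T cell", "Tcell", "T"),
    lower_q = 1 / 3, upper_q = 2 / 3,
    seed = 1L
  )
  overrides <- list()
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) {
      stop("config file not found: ", yaml_path, call. = FALSE)
    }
    y <- yaml::read_yaml(yaml_path)
    cfg[names(y)] <- y
    overrides <- c(overrides, y)
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  overrides <- c(overrides, dots)
  thresholds <- c("z_threshold", "p_threshold", "fdr_threshold",
                  "combined_lt", "maxdiff_lt", "min_malignant", "min_total",
                  "benefit_cutoff_months")
  if (any(unlist(cfg[thresholds]) <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  cfg$overrides <- overrides
  structure(cfg, class = c("run_config", "list"))
}

collect_warnings <- function(expr) {
  warns <- character()
  msgs <- character()
  val <- withCallingHandlers(
    expr,
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  list(value = val, warnings = warns, messages = msgs)
}

write_manifest <- function(out_dir, command, config, inputs = character(),
                           warnings = character(), notes = list()) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("immex")),
    seed = config$seed,
    config = config[setdiff(names(config), "overrides")],
    overrides = config$overrides,
    inputs = as.list(if (length(inputs))
      tools::md5sum(inputs) else character()),
    warnings = warnings,
    notes = notes
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

check_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(paths)
}

#' Write a synthetic study to disk
#'
#' Generates a bulk cohort, a single-cell cohort, and a response table from a
#' [synth_config()] and writes them in the same formats the readers consume
#' (expression TSV, annotation TSV, directional GMT, response CSV), plus the
#' ground truth as JSON and a run manifest. Reruns with the same
#' configuration are byte-identical.
#'
#' @param synth A [synth_config()].
#' @param out_dir Output directory (created).
#' @param tci_signature Signature used for the bulk inflamed shift; defaults
#'   to a 160-gene synthetic placeholder.
#' @param pathways Pathway set to write (defaults to
#'   [synthetic_pathways()] with 10 pathways).
#' @param config A [run_config()] recorded in the manifest.
#' @return Named list of written paths, invisibly.
#' @export
run_simulate <- function(synth, out_dir, tci_signature = NULL,
                         pathways = NULL, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(tci_signature)) {
    tci_signature <- gene_signature("TCI_SYNTHETIC",
                                    sprintf("TCI%03d", 1:160))
  }
  config$seed <- synth$seed
  res <- collect_warnings({
    universe <- build_universe(synth, tci_signature$genes)
    if (is.null(pathways)) {
      pathways <- synthetic_pathways(synth, gene_universe = universe)
    }
    bulk <- simulate_bulk_cohort(synth, tci_signature,
                                 gene_universe = universe)
    sc <- simulate_sc_cohort(synth, gene_universe = universe)
    resp <- simulate_response_table(synth)
    list(bulk = bulk, sc = sc, resp = resp, pathways = pathways)
  })
  v <- res$value
  paths <- c(
    bulk_expr = file.path(out_dir, "bulk_expression.tsv"),
    tci_gmt = file.path(out_dir, "tci_signature.gmt"),
    pathways_gmt = file.path(out_dir, "pathways.gmt"),
    response = file.path(out_dir, "response_table.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  write_expression_matrix(v$bulk$expr, paths[["bulk_expr"]])
  write_gmt(tci_signature, paths[["tci_gmt"]])
  write_directional_gmt(v$pathways, paths[["pathways_gmt"]])
  write_response_table(v$resp, paths[["response"]])
  sc_paths <- write_cell_cohort(v$sc$cohort, file.path(out_dir, "cells"))
  truth <- list(
    bulk_inflamed = as.list(v$bulk$truth$inflamed),
    sc_tcell_fraction = as.list(v$sc$truth$tcell_fraction),
    sc_group = as.list(v$sc$truth$group),
    planted = v$sc$truth$planted,
    gene_shift = as.list(v$sc$truth$gene_shift)
  )
  jsonlite::write_json(truth, paths[["ground_truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_manifest(out_dir, "simulate", config, warnings = res$warnings,
                 notes = list(messages = res$messages))
  invisible(c(paths, sc_paths))
}

#' Score a bulk cohort end to end
#'
#' Reads an expression matrix, a signature GMT and a directional pathway GMT;
#' writes per-sample signature scores and phenotype classes, per-pathway
#' scores, activation z-scores contrasting non-inflamed vs inflamed samples,
#' per-sample activation calls, a JSON summary and a manifest.
#'
#' @param expr_path,tci_gmt_path,pathways_gmt_path Input files.
#' @param out_dir Output directory (created).
#' @param config A [run_config()].
#' @param genes_as Orientation of the expression file (see
#'   [read_expression_matrix()]).
#' @return Named list of written paths, invisibly.
#' @export
run_score_bulk <- function(expr_path, tci_gmt_path, pathways_gmt_path,
                           out_dir, config = run_config(),
                           genes_as = "rows") {
  check_inputs(c(expr_path, tci_gmt_path, pathways_gmt_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- collect_warnings({
    expr <- read_expression_matrix(expr_path, genes_as = genes_as)
    sig <- read_gmt(tci_gmt_path)[[1]]
    pathways <- read_directional_gmt(pathways_gmt_path)
    classes <- classify_tci(tci_score(expr, sig),
                            lower_q = config$lower_q,
                            upper_q = config$upper_q)
    a <- classes$sample_id[classes$phenotype == "non_inflamed"]
    b <- classes$sample_id[classes$phenotype == "inflamed"]
    zs <- purrr::map_dfr(pathways, activation_zscore, expr = expr,
                         samples_a = a, samples_b = b,
                         z_threshold = config$z_threshold,
                         p_threshold = config$p_threshold)
    scores <- purrr::map_dfr(pathways, pathway_score_bulk, expr = expr,
                             signed = config$signed_bulk)
    calls <- purrr::map_dfr(pathways, function(pw) {
      dplyr::mutate(pathway_activation_call(expr, pw),
                    pathway = pw$regulator)
    })
    cors <- correlate_pathways_with_tci(expr, pathways, sig,
                                        signed = config$signed_bulk)
    n_act <- calls |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(n_activated = sum(.data$active), .groups = "drop")
    reg_df <- dplyr::inner_join(classes, n_act, by = "sample_id")
    reg <- cooccurrence_regression(reg_df, tci = "score",
                                   n_activated = "n_activated")
    list(classes = classes, zs = zs, scores = scores, calls = calls,
         cors = cors, reg = reg)
  })
  v <- res$value
  paths <- c(
    tci = file.path(out_dir, "tci_classes.tsv"),
    zscores = file.path(out_dir, "pathway_activation_z.tsv"),
    scores = file.path(out_dir, "pathway_scores.tsv"),
    calls = file.path(out_dir, "pathway_activation_calls.tsv"),
    correlations = file.path(out_dir, "pathway_tci_correlation.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  readr::write_tsv(v$classes, paths[["tci"]], progress = FALSE)
  readr::write_tsv(v$zs, paths[["zscores"]], progress = FALSE)
  readr::write_tsv(v$scores, paths[["scores"]], progress = FALSE)
  readr::write_tsv(v$calls, paths[["calls"]], progress = FALSE)
  readr::write_tsv(v$cors, paths[["correlations"]], progress = FALSE)
  jsonlite::write_json(
    list(n_samples = nrow(v$classes),
         phenotype_counts = as.list(table(v$classes$phenotype)),
         n_pathways = nrow(v$zs),
         n_activated = sum(v$zs$activated),
         cooccurrence_regression = as.list(v$reg)),
    paths[["summary"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "score-bulk", config,
                 inputs = c(expr_path, tci_gmt_path, pathways_gmt_path),
                 warnings = res$warnings,
                 notes = list(messages = res$messages))
  invisible(paths)
}

#' Score a single-cell cohort end to end
#'
#' Reads a cell cohort and a directional pathway GMT; applies the
#' malignant/total cell filters, computes T cell fractions and infiltration
#' groups, per-cell pathway scores, the mixed-model group contrasts with
#' BH-FDR, and per-tumor p38 activation scores on the malignant-cell
#' pseudobulk; writes TSV outputs, a JSON summary and a manifest.
#'
#' @param matrix_path,annotations_path Cohort input (see
#'   [read_cell_cohort()]).
#' @param pathways_gmt_path Directional GMT of pathway definitions.
#' @param out_dir Output directory (created).
#' @param config A [run_config()].
#' @param genes_path,barcodes_path Label files for `.mtx` input.
#' @return Named list of written paths, invisibly.
#' @export
run_score_cells <- function(matrix_path, annotations_path, pathways_gmt_path,
                            out_dir, config = run_config(),
                            genes_path = NULL, barcodes_path = NULL) {
  check_inputs(c(matrix_path, annotations_path, pathways_gmt_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- collect_warnings({
    cohort <- read_cell_cohort(matrix_path, annotations_path,
                               genes_path = genes_path,
                               barcodes_path = barcodes_path)
    pathways <- read_directional_gmt(pathways_gmt_path)
    filt <- filter_tumors(cohort, min_malignant = config$min_malignant,
                          min_total = config$min_total)
    kept <- subset_cells(cohort, tumors = filt$tumor_name[filt$kept])
    fr <- tcell_fraction(kept, tcell_labels = config$tcell_labels)
    assignment <- assign_infiltration_groups(fr, split = config$split)
    per_cell <- purrr::map_dfr(pathways, pathway_score_cells, cohort = kept,
                               signed = config$signed_sc)
    comps <- compare_groups_all(kept, pathways, assignment,
                                malignant_only = config$malignant_only,
                                signed = config$signed_sc,
                                fdr_threshold = config$fdr_threshold)
    pb <- pseudobulk(kept, cells = "malignant")
    p38 <- tryCatch(p38_score_tumors(pb), error = function(e) NULL)
    list(filt = filt, fr = fr, assignment = assignment,
         per_cell = per_cell, comps = comps, p38 = p38)
  })
  v <- res$value
  paths <- c(
    filters = file.path(out_dir, "tumor_filters.tsv"),
    groups = file.path(out_dir, "infiltration_groups.tsv"),
    cell_scores = file.path(out_dir, "cell_pathway_scores.tsv"),
    comparisons = file.path(out_dir, "group_comparisons.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  readr::write_tsv(v$filt, paths[["filters"]], progress = FALSE)
  readr::write_tsv(v$assignment, paths[["groups"]], progress = FALSE)
  readr::write_tsv(v$per_cell, paths[["cell_scores"]], progress = FALSE)
  readr::write_tsv(v$comps, paths[["comparisons"]], progress = FALSE)
  if (!is.null(v$p38)) {
    paths <- c(paths, p38 = file.path(out_dir, "p38_tumor_scores.tsv"))
    readr::write_tsv(v$p38, paths[["p38"]], progress = FALSE)
  }
  jsonlite::write_json(
    list(n_tumors_input = nrow(v$filt),
         n_tumors_kept = sum(v$filt$kept),
         excluded_tumors = v$filt$tumor_name[!v$filt$kept],
         malignant_only = config$malignant_only,
         n_pathways = nrow(v$comps),
         n_significant = sum(v$comps$significant, na.rm = TRUE)),
    paths[["summary"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "score-cells", config,
                 inputs = c(matrix_path, annotations_path, pathways_gmt_path),
                 warnings = res$warnings,
                 notes = list(messages = res$messages))
  invisible(paths)
}

#' Integrate three evidence streams and write the prioritization
#'
#' Reads three two-column TSVs (`pathway`, `value`) — bulk activation
#' z-scores, anti-correlation coefficients, and single-cell contrast
#' p-values — and writes the sorted priority table plus the JSON pass list.
#'
#' @param bulk_path,anticor_path,sc_path Stream input TSVs.
#' @param out_dir Output directory (created).
#' @param config A [run_config()].
#' @return Named list of written paths, invisibly.
#' @export
run_prioritize <- function(bulk_path, anticor_path, sc_path, out_dir,
                           config = run_config()) {
  check_inputs(c(bulk_path, anticor_path, sc_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  read_stream <- function(p) readr::read_tsv(p, show_col_types = FALSE,
                                             progress = FALSE)
  res <- collect_warnings({
    prioritize(read_stream(bulk_path), read_stream(anticor_path),
               read_stream(sc_path), combined_lt = config$combined_lt,
               maxdiff_lt = config$maxdiff_lt, sc_rank = config$sc_rank)
  })
  paths <- c(priorities = file.path(out_dir, "priorities.tsv"),
             passes = file.path(out_dir, "pass_list.json"))
  readr::write_tsv(res$value, paths[["priorities"]], progress = FALSE)
  jsonlite::write_json(res$value$pathway[res$value$passes],
                       paths[["passes"]], pretty = TRUE)
  write_manifest(out_dir, "prioritize", config,
                 inputs = c(bulk_path, anticor_path, sc_path),
                 warnings = res$warnings,
                 notes = list(messages = res$messages))
  invisible(paths)
}

#' Summarize a trial response table and write the outputs
#'
#' Reads a subject response CSV and writes the response-rate summary JSON,
#' the waterfall plotting table, the Kaplan-Meier table of benefit duration
#' (subjects without progression-independent event treated as censored), and
#' a manifest.
#'
#' @param response_path Input CSV (see [read_response_table()]).
#' @param out_dir Output directory (created).
#' @param config A [run_config()].
#' @return Named list of written paths, invisibly.
#' @export
run_trial_summary <- function(response_path, out_dir,
                              config = run_config()) {
  check_inputs(response_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- collect_warnings({
    rows <- read_response_table(response_path)
    summ <- summarize_trial(rows,
                            benefit_cutoff_months = config$benefit_cutoff_months)
    wf <- waterfall_table(rows,
                          benefit_cutoff_months = config$benefit_cutoff_months)
    ev <- rows[rows$evaluable, , drop = FALSE]
    km <- kaplan_meier(tibble::tibble(
      time = ev$benefit_months,
      event = ev$new_therapy_within_1yr | ev$best_pct_change >= 20))
    list(rows = rows, summ = summ, wf = wf, km = km)
  })
  v <- res$value
  paths <- c(summary = file.path(out_dir, "trial_summary.json"),
             waterfall = file.path(out_dir, "waterfall.tsv"),
             km = file.path(out_dir, "kaplan_meier.tsv"))
  jsonlite::write_json(as.list(v$summ), paths[["summary"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_tsv(v$wf, paths[["waterfall"]], progress = FALSE)
  readr::write_tsv(v$km, paths[["km"]], progress = FALSE)
  write_manifest(out_dir, "trial-summary", config, inputs = response_path,
                 warnings = res$warnings,
                 notes = list(messages = res$messages))
  invisible(paths)
}
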
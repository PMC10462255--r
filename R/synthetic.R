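#' Configuration for the synthetic cohort generators
#'
#' Bundles all knobs of the synthetic bulk, single-cell, and trial-response
#' generators. Defaults emulate the statistical structure of the real study
#' cohorts at desk scale: log-scale Gaussian expression noise around fixed
#' per-gene baselines, per-tumor baseline offsets shared by all cells of a
#' tumor, tumor cell-dominated cell-type mixtures with a variable T cell
#' fraction, and direction-aware pathway shifts planted in malignant cells of
#' low-infiltration tumors.
#'
#' @param seed Integer RNG seed; a fixed seed gives identical output across
#'   runs (R's default Mersenne-Twister generator).
#' @param n_tumors Number of tumors (bulk samples or single-cell patients).
#' @param n_genes Size of the gene universe (signature / pathway target genes
#'   are embedded in it).
#' @param frac_inflamed Proportion of bulk tumors given the T cell-inflamed
#'   phenotype.
#' @param planted_pathways List of `list(pathway = <pathway_definition>,
#'   delta = <log2 shift>)`; targets of planted pathways are shifted by
#'   `+delta` (up-targets) / `-delta` (down-targets) in non-inflamed bulk
#'   tumors and in malignant cells of low-infiltration tumors.
#' @param delta_tci Log2 shift added to T cell-inflamed signature genes in
#'   inflamed bulk tumors.
#' @param noise_sd Gaussian noise SD on the log2 scale (per value).
#' @param tumor_effect_sd SD of the per-tumor baseline offset shared by all
#'   cells/genes of a tumor (inter-patient heterogeneity driving the random
#'   intercept of the mixed model).
#' @param cells_per_tumor Length-2 integer range; per-tumor cell counts are
#'   drawn uniformly from it.
#' @param celltype_proportions Named proportions of the non-T cell
#'   compartment; must sum to 1. The type `"malignant"` marks malignant cells.
#' @param tcell_fraction_range Length-2 range of per-tumor T cell fractions.
#'   Draws are bimodal — half the tumors from the lower 35% of the range,
#'   half from the upper 35% — emulating the extreme-phenotype contrast with
#'   an identifiable low/high ground truth.
#' @param n_subjects Number of subjects for the response-table generator.
#' @param response_mixture Named weights `(responder, stable, progressor)`
#'   for the best-percent-change mixture; must sum to 1.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_tumors = 60L,
                         n_genes = 300L,
                         frac_inflamed = 1 / 3,
                         planted_pathways = list(),
                         delta_tci = 2,
                         noise_sd = 0.5,
                         tumor_effect_sd = 0.2,
                         cells_per_tumor = c(100L, 300L),
                         celltype_proportions = c(malignant = 0.50,
                                                  fibroblast = 0.20,
                                                  macrophage = 0.15,
                                                  B_cell = 0.15),
                         tcell_fraction_range = c(0.02, 0.40),
                         n_subjects = 100L,
                         response_mixture = c(responder = 0.2,
                                              stable = 0.4,
                                              progressor = 0.4)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (abs(sum(celltype_proportions) - 1) > 1e-9) {
    stop("celltype_proportions must sum to 1", call. = FALSE)
  }
  if (abs(sum(response_mixture) - 1) > 1e-9) {
    stop("response_mixture weights must sum to 1", call. = FALSE)
  }
  if (any(celltype_proportions < 0) || any(response_mixture < 0)) {
    stop("proportions must be nonnegative", call. = FALSE)
  }
  stopifnot(n_tumors >= 1, n_genes >= 1, noise_sd > 0, tumor_effect_sd >= 0,
            frac_inflamed >= 0, frac_inflamed <= 1,
            length(cells_per_tumor) == 2L, cells_per_tumor[1] >= 1,
            cells_per_tumor[2] >= cells_per_tumor[1],
            length(tcell_fraction_range) == 2L,
            tcell_fraction_range[1] >= 0, tcell_fraction_range[2] <= 1,
            tcell_fraction_range[2] >= tcell_fraction_range[1])
  for (pp in planted_pathways) {
    if (!inherits(pp$pathway, "pathway_def") || !is.finite(pp$delta)) {
      stop("each planted pathway needs a pathway_def and a finite delta",
           call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_tumors = as.integer(n_tumors),
         n_genes = as.integer(n_genes), frac_inflamed = frac_inflamed,
         planted_pathways = planted_pathways, delta_tci = delta_tci,
         noise_sd = noise_sd, tumor_effect_sd = tumor_effect_sd,
         cells_per_tumor = as.integer(cells_per_tumor),
         celltype_proportions = celltype_proportions,
         tcell_fraction_range = tcell_fraction_range,
         n_subjects = as.integer(n_subjects),
         response_mixture = response_mixture),
    class = "synth_config"
  )
}

planted_defs <- function(config) lapply(config$planted_pathways, `[[`, "pathway")
planted_deltas <- function(config) {
  vapply(config$planted_pathways, `[[`, numeric(1), "delta")
}

# Gene universe: planted targets and signature genes first, filler genes after.
build_universe <- function(config, extra_genes = character()) {
  needed <- unique(c(extra_genes,
                     unlist(lapply(planted_defs(config),
                                   function(p) p$targets$gene))))
  if (length(needed) > config$n_genes) {
    stop("n_genes (", config$n_genes, ") smaller than the ", length(needed),
         " signature/pathway genes to embed", call. = FALSE)
  }
  n_fill <- config$n_genes - length(needed)
  c(needed, sprintf("G%04d", seq_len(n_fill)))
}

# Per-gene signed shift implied by the planted pathways (sums over pathways
# sharing a target).
planted_shifts <- function(config) {
  shift <- numeric(0)
  for (pp in config$planted_pathways) {
    s <- target_signs(pp$pathway) * pp$delta
    for (g in names(s)) shift[g] <- (if (g %in% names(shift)) shift[g] else 0) + s[[g]]
  }
  shift
}

#' Generate a synthetic bulk expression cohort with planted ground truth
#'
#' Baseline log2 expression is `Normal(mu_g, noise_sd)` with per-gene means
#' `mu_g ~ Normal(5, 1)` drawn once per cohort, plus a per-tumor offset
#' `Normal(0, tumor_effect_sd)`. A `frac_inflamed` fraction of tumors is
#' labelled inflamed and has the T cell-inflamed signature genes shifted by
#' `+delta_tci`; in the remaining (non-inflamed) tumors each planted pathway's
#' targets are shifted by `+delta` (up) / `-delta` (down).
#'
#' @param config A [synth_config()].
#' @param tci_signature [gene_signature()] used for the inflamed shift.
#' @param gene_universe Optional explicit gene universe; signature and planted
#'   target genes must be contained in it (error lists any missing symbols).
#' @return A list with `expr` (samples x genes matrix) and `truth` (list with
#'   `inflamed` named logical, `mu`, `gene_shift` named signed shifts, and
#'   `planted` pathway names).
#' @export
simulate_bulk_cohort <- function(config, tci_signature, gene_universe = NULL) {
  stopifnot(inherits(config, "synth_config"),
            inherits(tci_signature, "gene_signature"))
  if (is.null(gene_universe)) {
    gene_universe <- build_universe(config, tci_signature$genes)
  } else {
    miss <- setdiff(c(tci_signature$genes,
                      unlist(lapply(planted_defs(config),
                                    function(p) p$targets$gene))),
                    gene_universe)
    if (length(miss)) {
      stop("gene(s) missing from universe: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  n <- config$n_tumors
  g <- length(gene_universe)
  samples <- sprintf("S%03d", seq_len(n))
  mu <- stats::rnorm(g, mean = 5, sd = 1)
  names(mu) <- gene_universe
  tumor_off <- stats::rnorm(n, 0, config$tumor_effect_sd)
  n_inf <- round(config$frac_inflamed * n)
  inflamed <- stats::setNames(rep(FALSE, n), samples)
  if (n_inf > 0) inflamed[sample.int(n, n_inf)] <- TRUE

  expr <- matrix(stats::rnorm(n * g, sd = config$noise_sd), nrow = n,
                 dimnames = list(samples, gene_universe))
  expr <- sweep(expr, 2, mu, `+`) + tumor_off
  tci_idx <- match(tci_signature$genes, gene_universe)
  expr[inflamed, tci_idx] <- expr[inflamed, tci_idx] + config$delta_tci
  shift <- planted_shifts(config)
  if (length(shift)) {
    sh_idx <- match(names(shift), gene_universe)
    expr[!inflamed, sh_idx] <- sweep(expr[!inflamed, sh_idx, drop = FALSE],
                                     2, shift, `+`)
  }
  list(expr = expr,
       truth = list(inflamed = inflamed, mu = mu, gene_shift = shift,
                    planted = vapply(planted_defs(config), `[[`, "",
                                     "regulator")))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic single-cell cohort with planted ground truth
#'
#' Per tumor, a T cell fraction is drawn bimodally from
#' `tcell_fraction_range` (half the tumors from the lower part of the range,
#' half from the upper) and cell types are sampled multinomially with the
#' `"T cell"` proportion set to that fraction (other types scaled by the
#' remainder). Expression is log-normalized-scale Gaussian noise around the
#' per-gene baselines plus a shared per-tumor offset. Tumors whose drawn
#' fraction is at or below the cohort median form the low-infiltration ground
#' truth; their malignant cells carry the planted, direction-aware pathway
#' shifts.
#'
#' @param config A [synth_config()].
#' @param gene_universe Optional explicit gene universe (planted targets must
#'   be contained in it).
#' @return A list with `cohort` (a [cell_cohort()]) and `truth` (list with
#'   `tcell_fraction`, `group` ("low"/"high", both named by tumor),
#'   `gene_shift`, `planted`).
#' @export
simulate_sc_cohort <- function(config, gene_universe = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(gene_universe)) gene_universe <- build_universe(config)
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  n_t <- config$n_tumors
  tumors <- sprintf("T%02d", seq_len(n_t))
  g <- length(gene_universe)
  mu <- stats::rnorm(g, 5, 1)
  names(mu) <- gene_universe
  tumor_off <- stats::setNames(stats::rnorm(n_t, 0, config$tumor_effect_sd),
                               tumors)
  # bimodal fractions: half the tumors draw from the lower 35% of the range,
  # half from the upper 35%, so the low/high ground truth is identifiable
  # from observed cell counts (a width-0 range degenerates to a point mass)
  r <- config$tcell_fraction_range
  w <- diff(r)
  n_low <- ceiling(n_t / 2)
  is_low <- rep(FALSE, n_t)
  is_low[sample.int(n_t, n_low)] <- TRUE
  u <- stats::runif(n_t)
  fr <- ifelse(is_low, r[1] + 0.35 * w * u, r[2] - 0.35 * w * u)
  names(fr) <- tumors
  group <- stats::setNames(ifelse(fr <= stats::median(fr), "low", "high"),
                           tumors)
  lo <- config$cells_per_tumor[1]
  hi <- config$cells_per_tumor[2]
  n_cells <- lo + sample.int(hi - lo + 1L, n_t, replace = TRUE) - 1L
  if (any(n_cells < 1)) stop("zero cells requested", call. = FALSE)

  types <- c(names(config$celltype_proportions), "T cell")
  shift <- planted_shifts(config)
  sh_idx <- match(names(shift), gene_universe)

  blocks <- vector("list", n_t)
  anns <- vector("list", n_t)
  for (i in seq_len(n_t)) {
    nc <- n_cells[i]
    probs <- c(config$celltype_proportions * (1 - fr[i]), fr[i])
    ct <- sample(types, nc, replace = TRUE, prob = probs)
    vals <- matrix(stats::rnorm(nc * g, sd = config$noise_sd), nrow = nc)
    vals <- sweep(vals, 2, mu, `+`) + tumor_off[i]
    malignant <- ct == "malignant"
    if (length(shift) && group[i] == "low" && any(malignant)) {
      vals[malignant, sh_idx] <- sweep(vals[malignant, sh_idx, drop = FALSE],
                                       2, shift, `+`)
    }
    ids <- sprintf("%s_C%04d", tumors[i], seq_len(nc))
    rownames(vals) <- ids
    blocks[[i]] <- vals
    anns[[i]] <- tibble::tibble(cell_id = ids, tumor_name = tumors[i],
                                cell_type = ct, is_malignant = malignant)
  }
  values <- do.call(rbind, blocks)
  colnames(values) <- gene_universe
  cohort <- cell_cohort(values, dplyr::bind_rows(anns))
  list(cohort = cohort,
       truth = list(tcell_fraction = fr, group = group, gene_shift = shift,
                    planted = vapply(planted_defs(config), `[[`, "",
                                     "regulator")))
}

#' Generate a synthetic subject response table
#'
#' Each subject is drawn from a three-component mixture: responders with best
#' percent change `Uniform(-100, -30)` and benefit `Uniform(8, 30)` months,
#' stable disease `Uniform(-29, 19)` with benefit `Uniform(2, 12)`, and
#' progressors `Uniform(20, 100)` with benefit `Uniform(0.5, 4)`. Responders
#' are irRECIST-confirmed; two thirds of them (in expectation) are also
#' RECIST-confirmed, mirroring the typical gap between the two criteria.
#'
#' @param config A [synth_config()]; uses `n_subjects`, `response_mixture`,
#'   `seed`.
#' @return A tibble with one row per subject: `subject_id`,
#'   `best_pct_change`, `confirmed_recist`, `confirmed_irrecist`,
#'   `benefit_months`, `new_therapy_within_1yr`, `evaluable`.
#' @export
simulate_response_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_subjects
  if (n < 1) stop("n_subjects must be >= 1", call. = FALSE)
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  cls <- sample(names(config$response_mixture), n, replace = TRUE,
                prob = config$response_mixture)
  pct <- numeric(n); lo <- numeric(n); hi <- numeric(n)
  lo[cls == "responder"] <- -100; hi[cls == "responder"] <- -30
  lo[cls == "stable"] <- -29;     hi[cls == "stable"] <- 19
  lo[cls == "progressor"] <- 20;  hi[cls == "progressor"] <- 100
  pct <- stats::runif(n, lo, hi)
  benefit <- numeric(n)
  benefit[cls == "responder"] <- stats::runif(sum(cls == "responder"), 8, 30)
  benefit[cls == "stable"] <- stats::runif(sum(cls == "stable"), 2, 12)
  benefit[cls == "progressor"] <- stats::runif(sum(cls == "progressor"), 0.5, 4)
  irr <- cls == "responder"
  rec <- irr & stats::runif(n) < 2 / 3
  tibble::tibble(
    subject_id = sprintf("SUBJ%03d", seq_len(n)),
    best_pct_change = pct,
    confirmed_recist = rec,
    confirmed_irrecist = irr,
    benefit_months = benefit,
    new_therapy_within_1yr = benefit < 9,
    evaluable = TRUE
  )
}

#' Build a set of synthetic directional pathway definitions
#'
#' Convenience for simulations: draws `n_pathways` pathway definitions with
#' non-overlapping targets from a config's gene universe, a fixed fraction of
#' them down-regulated targets.
#'
#' @param config A [synth_config()].
#' @param n_pathways Number of pathways.
#' @param n_targets Targets per pathway.
#' @param frac_down Fraction of targets per pathway with direction `"down"`.
#' @param gene_universe Optional explicit universe to draw filler genes from.
#' @return Named list of [pathway_definition()] objects; planted pathway
#'   definitions from the config come first, decoys (named `DECOY_k`) after.
#' @export
synthetic_pathways <- function(config, n_pathways = 10L, n_targets = 12L,
                               frac_down = 0.25, gene_universe = NULL) {
  if (is.null(gene_universe)) gene_universe <- build_universe(config)
  planted <- planted_defs(config)
  used <- unlist(lapply(planted, function(p) p$targets$gene))
  pool <- setdiff(gene_universe, used)
  n_decoy <- n_pathways - length(planted)
  if (n_decoy < 0) stop("n_pathways smaller than planted set", call. = FALSE)
  if (n_decoy * n_targets > length(pool)) {
    stop("gene universe too small for the requested decoy pathways",
         call. = FALSE)
  }
  n_dn <- round(frac_down * n_targets)
  dirs <- c(rep("down", n_dn), rep("up", n_targets - n_dn))
  decoys <- lapply(seq_len(n_decoy), function(k) {
    genes <- pool[((k - 1) * n_targets + 1):(k * n_targets)]
    pathway_definition(sprintf("DECOY_%02d", k), genes, dirs,
                       source = "synthetic decoy")
  })
  out <- c(planted, decoys)
  stats::setNames(out, vapply(out, `[[`, "", "regulator"))
}

#' Run the full prioritization pipeline on one synthetic study
#'
#' End-to-end validation harness: generates a bulk cohort and a single-cell
#' cohort sharing one planted pathway among decoys, computes the three
#' evidence streams (bulk activation z contrasting non-inflamed vs inflamed
#' tumors, continuous anti-correlation with the T cell-inflamed score, and
#' the single-cell mixed-model low-vs-high infiltration contrast), and
#' integrates them with [prioritize()].
#'
#' @param seed Integer seed controlling every random draw.
#' @param delta Planted log2 effect size (default 1.5).
#' @param n_pathways Total pathways scored (1 planted + decoys).
#' @param n_tumors_sc,cells_per_tumor Single-cell cohort size (defaults: 5
#'   tumors of 300 cells, the scale of a per-patient scRNA-seq study).
#' @param n_tumors_bulk Bulk cohort size (default 60).
#' @return A list: `zscores`, `correlations`, `comparisons` (per-pathway
#'   tibbles), `priorities` (from [prioritize()]), and `planted` (the planted
#'   pathway's name).
#' @export
synthetic_study <- function(seed, delta = 1.5, n_pathways = 10L,
                            n_tumors_sc = 5L,
                            cells_per_tumor = c(300L, 300L),
                            n_tumors_bulk = 60L) {
  planted <- pathway_definition(
    "PLANTED", sprintf("PT%02d", 1:12),
    c(rep("up", 9), rep("down", 3)), source = "synthetic planted pathway")
  base <- list(planted_pathways = list(list(pathway = planted, delta = delta)),
               n_genes = 300L)
  tci <- gene_signature("TCI_SYNTHETIC", sprintf("TCI%03d", 1:160))

  cfg_sc <- synth_config(seed = seed, n_tumors = n_tumors_sc,
                         n_genes = base$n_genes,
                         cells_per_tumor = cells_per_tumor,
                         planted_pathways = base$planted_pathways)
  cfg_bulk <- synth_config(seed = seed + 1L, n_tumors = n_tumors_bulk,
                           n_genes = base$n_genes,
                           planted_pathways = base$planted_pathways)
  universe <- build_universe(cfg_bulk, tci$genes)
  pathways <- synthetic_pathways(cfg_bulk, n_pathways = n_pathways,
                                 gene_universe = universe)

  bulk <- simulate_bulk_cohort(cfg_bulk, tci, gene_universe = universe)
  classes <- classify_tci(tci_score(bulk$expr, tci))
  a <- classes$sample_id[classes$phenotype == "non_inflamed"]
  b <- classes$sample_id[classes$phenotype == "inflamed"]
  zs <- purrr::map_dfr(pathways, activation_zscore, expr = bulk$expr,
                       samples_a = a, samples_b = b)
  cors <- correlate_pathways_with_tci(bulk$expr, pathways, tci)

  sc <- simulate_sc_cohort(cfg_sc, gene_universe = universe)
  fr <- tcell_fraction(sc$cohort)
  assignment <- assign_infiltration_groups(fr)
  comps <- compare_groups_all(sc$cohort, pathways, assignment)

  pri <- prioritize(stats::setNames(zs$zscore, zs$pathway),
                    stats::setNames(cors$r, cors$pathway),
                    stats::setNames(comps$p, comps$pathway))
  list(zscores = zs, correlations = cors, comparisons = comps,
       priorities = pri, planted = planted$regulator)
}
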
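test_that("per-cell scores are signed means and linear in expression", {
  genes <- c("A", "B")
  ann <- tibble::tibble(cell_id = c("c1", "c2"), tumor_name = "T01",
                        cell_type = "malignant", is_malignant = TRUE)
  vals <- matrix(c(3, 1, 3, 1), nrow = 2, dimnames = list(ann$cell_id, genes))
  co <- cell_cohort(vals, ann)
  pw_up <- pathway_definition("P", c("A", "B"))
  expect_equal(pathway_score_cells(co, pw_up)$score, c(3, 1))

  pw_mix <- pathway_definition("P", c("A", "B"), c("up", "down"))
  expect_equal(pathway_score_cells(co, pw_mix)$score, c(0, 0))

  # random cohort vs brute force, plus linearity score(x+y)=score(x)+score(y)
  co1 <- make_test_cohort(3, 20, seed = 1)
  co2 <- make_test_cohort(3, 20, seed = 2)
  pw <- pathway_definition("P", sprintf("G%03d", 1:7),
                           c(rep("up", 5), "down", "down"))
  s1 <- pathway_score_cells(co1, pw)$score
  expect_equal(s1, unname(signed_score_brute(co1$values, pw$targets$gene,
                                             pw$targets$direction)),
               tolerance = 1e-12)
  sum_co <- cell_cohort(co1$values + co2$values, co1$cells)
  expect_equal(pathway_score_cells(sum_co, pw)$score,
               s1 + pathway_score_cells(co2, pw)$score, tolerance = 1e-12)

  expect_error(pathway_score_cells(co, pathway_definition("Q", "ZZ")),
               "no target")
})

test_that("tumor filters apply the inclusive 40/100 bounds", {
  mk <- function(n_mal, n_tot, tumor) {
    tibble::tibble(cell_id = sprintf("%s_c%03d", tumor, seq_len(n_tot)),
                   tumor_name = tumor,
                   cell_type = c(rep("malignant", n_mal),
                                 rep("T cell", n_tot - n_mal)),
                   is_malignant = c(rep(TRUE, n_mal),
                                    rep(FALSE, n_tot - n_mal)))
  }
  ann <- dplyr::bind_rows(mk(39, 500, "T01"), mk(40, 100, "T02"),
                          mk(200, 300, "T03"))
  ann3 <- dplyr::bind_rows(mk(99, 99, "T04"))
  ann <- dplyr::bind_rows(ann, ann3)
  vals <- matrix(0, nrow = nrow(ann), ncol = 2,
                 dimnames = list(ann$cell_id, c("A", "B")))
  co <- cell_cohort(vals, ann)
  expect_message(filt <- filter_tumors(co), "excluding")
  expect_equal(setNames(filt$kept, filt$tumor_name),
               c(T01 = FALSE, T02 = TRUE, T03 = TRUE, T04 = FALSE))
})

test_that("T cell fractions count labels over all cells, order-invariantly", {
  co <- make_test_cohort(2, 100, seed = 5,
                         types = c("malignant", "T cell", "fibroblast",
                                   "malignant"))
  fr <- tcell_fraction(co)
  expect_equal(fr$fraction, fr$n_tcells / fr$n_cells)
  expect_equal(fr$n_cells, c(100, 100))

  shuf <- sample(nrow(co$values))
  co_sh <- cell_cohort(co$values[shuf, ], co$cells[shuf, ])
  fr_sh <- tcell_fraction(co_sh)
  expect_equal(dplyr::arrange(fr_sh, tumor_name), fr)

  # zero T cells and unknown label set
  co0 <- make_test_cohort(2, 10, types = c("malignant", "fibroblast"))
  expect_warning(fr0 <- tcell_fraction(co0), "no cell matches")
  expect_true(all(fr0$fraction == 0))
})

test_that("infiltration grouping supports median and extreme modes", {
  fr <- c(T01 = 0.01, T02 = 0.05, T03 = 0.2, T04 = 0.4)
  asg <- assign_infiltration_groups(fr)
  expect_equal(setNames(asg$group, asg$tumor_name),
               c(T01 = "low", T02 = "low", T03 = "high", T04 = "high"))

  fr5 <- c(fr, T05 = 0.3)
  ext <- assign_infiltration_groups(fr5, mode = "extreme", k = 1)
  expect_equal(sum(ext$group == "low"), 1)
  expect_equal(sum(ext$group == "high"), 1)
  expect_equal(sum(ext$group == "excluded"), 3)
  expect_equal(ext$group[ext$tumor_name == "T01"], "low")
  expect_equal(ext$group[ext$tumor_name == "T04"], "high")

  expect_error(assign_infiltration_groups(c(a = 0.2, b = 0.2)),
               "explicit assignment")
})

test_that("the mixed-model contrast separates groups and falls back sanely", {
  # clean separation: low tumors at 5, high at 0, tiny noise
  set.seed(3)
  ann <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:200),
    tumor_name = rep(sprintf("T%02d", 1:4), each = 50),
    cell_type = "malignant", is_malignant = TRUE)
  score <- c(rep(5, 100), rep(0, 100)) + rnorm(200, sd = 1e-3)
  df <- data.frame(score = score,
                   group = rep(c("low", "high"), each = 100),
                   tumor_name = ann$tumor_name)
  ct <- compare_groups_lmm(df)
  expect_equal(ct$estimate, 5, tolerance = 0.01)
  expect_lt(ct$p, 1e-10)

  td <- tidy(ct)
  expect_equal(td$estimate, ct$estimate)
  expect_true(is.data.frame(glance(ct)))

  # zero between-tumor variance triggers the flagged OLS fallback
  set.seed(4)
  df0 <- data.frame(score = rnorm(400),
                    group = rep(c("low", "high"), each = 200),
                    tumor_name = rep(sprintf("T%02d", 1:8), each = 50))
  ct0 <- compare_groups_lmm(df0)
  expect_true(ct0$singular_fallback)
  expect_equal(ct0$method, "ols")

  # preconditions
  expect_error(compare_groups_lmm(df[df$tumor_name %in%
                                       c("T01", "T03"), ]), "2 tumors")
  df_bad <- df
  df_bad$group[1] <- "high"
  expect_error(compare_groups_lmm(df_bad), "share one group")
})

test_that("p-values are invariant to tumor relabeling and cell order", {
  cfg <- synth_config(seed = 21, n_tumors = 6, n_genes = 30,
                      cells_per_tumor = c(40L, 60L))
  sim <- simulate_sc_cohort(cfg)
  pw <- pathway_definition("P", sprintf("G%04d", 1:8))
  sc <- pathway_score_cells(sim$cohort, pw)
  sc <- sc[sc$is_malignant, ]
  sc$group <- sim$truth$group[sc$tumor_name]
  p0 <- compare_groups_lmm(sc)$p

  relab <- sc
  relab$tumor_name <- paste0("X_", relab$tumor_name)
  expect_equal(compare_groups_lmm(relab)$p, p0, tolerance = 1e-8)

  perm <- sc[sample(nrow(sc)), ]
  expect_equal(compare_groups_lmm(perm)$p, p0, tolerance = 1e-8)
})

test_that("family-wise contrasts recover plants and match brute-force BH", {
  planted <- pathway_definition("PLANTED", sprintf("PT%02d", 1:8),
                                c(rep("up", 6), rep("down", 2)))
  cfg <- synth_config(seed = 31, n_tumors = 6, n_genes = 200,
                      cells_per_tumor = c(120L, 160L),
                      planted_pathways = list(list(pathway = planted,
                                                   delta = 1.5)))
  sim <- simulate_sc_cohort(cfg)
  pws <- synthetic_pathways(cfg, n_pathways = 8, n_targets = 8)
  asg <- assign_infiltration_groups(tcell_fraction(sim$cohort))
  res <- compare_groups_all(sim$cohort, pws, asg)
  expect_equal(res$pathway[which.min(res$q)], "PLANTED")
  expect_true(res$significant[res$pathway == "PLANTED"])
  expect_equal(res$q, bh_brute(res$p), tolerance = 1e-12)
  # q-values are monotone in p
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))

  # empty pathway list: empty result
  empty <- compare_groups_all(sim$cohort, list(), asg)
  expect_equal(nrow(empty), 0)
})

test_that("nested cell-type contrasts detect planted dominance", {
  set.seed(40)
  n_t <- 4
  ann <- tibble::tibble(
    cell_id = sprintf("c%04d", 1:400),
    tumor_name = rep(sprintf("T%02d", 1:n_t), each = 100),
    cell_type = rep(rep(c("malignant", "fibroblast"), each = 50), n_t),
    is_malignant = rep(rep(c(TRUE, FALSE), each = 50), n_t))
  tum_eff <- rep(rnorm(n_t, sd = 0.3), each = 100)
  score <- rnorm(400, sd = 0.4) + tum_eff +
    ifelse(ann$cell_type == "malignant", 2, 0)
  df <- data.frame(score = score, cell_type = ann$cell_type,
                   tumor_name = ann$tumor_name)
  ct <- compare_celltypes_nested(df, "malignant", "fibroblast")
  expect_equal(ct$estimate, 2, tolerance = 0.3)
  expect_lt(ct$p, 0.01)

  # null: identical distributions
  df_null <- df
  df_null$score <- rnorm(400) + tum_eff
  ct0 <- compare_celltypes_nested(df_null, "malignant", "fibroblast")
  expect_lt(abs(ct0$estimate), 0.3)

  expect_error(compare_celltypes_nested(df, "malignant", "absent_type"),
               "absent")
  df1 <- df[df$tumor_name == "T01", ]
  expect_error(compare_celltypes_nested(df1, "malignant", "fibroblast"),
               "fewer than 2 tumors")
})

test_that("p38 tumor scores are centered, flag degeneracy, and separate groups", {
  # centering identity on the malignant pseudobulk of a synthetic cohort
  cfg <- synth_config(seed = 51, n_tumors = 8, n_genes = 40,
                      cells_per_tumor = c(60L, 90L))
  sim <- simulate_sc_cohort(cfg)
  pb <- pseudobulk(sim$cohort)
  sig <- gene_signature("S12", sprintf("G%04d", 1:12))
  sc <- p38_score_tumors(pb, sig)
  expect_equal(mean(sc$score), 0, tolerance = 1e-10)

  # two identical tumors: all genes zero-variance -> error
  two <- matrix(5, nrow = 2, ncol = 12,
                dimnames = list(c("T1", "T2"), sprintf("G%04d", 1:12)))
  expect_error(expect_warning(p38_score_tumors(two, sig), "zero-variance"),
               "score undefined")
  expect_error(p38_score_tumors(two[1, , drop = FALSE], sig), "2 tumors")

  # planted +delta on the signature genes in low tumors separates groups
  p38pw <- pathway_definition("P38X", p38_signature()$genes)
  cfgd <- synth_config(seed = 52, n_tumors = 40, n_genes = 100,
                       cells_per_tumor = c(40L, 60L),
                       planted_pathways = list(list(pathway = p38pw,
                                                    delta = 1)))
  simd <- simulate_sc_cohort(cfgd)
  pbd <- pseudobulk(simd$cohort)
  scd <- p38_score_tumors(pbd, p38_signature())
  grp <- simd$truth$group[scd$tumor_name]
  expect_gt(mean(scd$score[grp == "low"]), mean(scd$score[grp == "high"]))
  w <- wilcox.test(scd$score[grp == "low"], scd$score[grp == "high"],
                   alternative = "greater")
  expect_lt(w$p.value, 0.05)
})
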
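test_that("signature scoring is the row mean over present signature genes", {
  expr <- matrix(c(1, 2, 3, 2), nrow = 2,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  sig <- gene_signature("S", c("A", "B"))
  expect_equal(tci_score(expr, sig)$score, c(2, 2))

  # constant sample
  expr2 <- matrix(4, nrow = 3, ncol = 5,
                  dimnames = list(paste0("s", 1:3), paste0("g", 1:5)))
  expect_equal(tci_score(expr2, gene_signature("S", paste0("g", 1:5)))$score,
               rep(4, 3))

  # random matrix vs brute-force row mean
  expr3 <- make_test_expr(20, sprintf("G%03d", 1:50))
  sig3 <- gene_signature("S", sprintf("G%03d", seq(3, 30, 3)))
  expect_equal(tci_score(expr3, sig3)$score,
               unname(rowMeans(expr3[, sig3$genes])), tolerance = 1e-12)

  expect_error(tci_score(expr, gene_signature("S", "ZZZ")), "no gene")
  # gene column order must not matter
  perm <- expr3[, sample(ncol(expr3))]
  expect_equal(tci_score(perm, sig3)$score, tci_score(expr3, sig3)$score)
})

test_that("quantile classification splits tertiles and handles degeneracy", {
  res <- classify_tci(setNames(1:9, paste0("s", 1:9)))
  expect_equal(as.vector(table(res$phenotype)), c(3, 3, 3))
  expect_equal(res$phenotype[res$score <= 3],
               factor(rep("non_inflamed", 3),
                      levels = levels(res$phenotype)))

  expect_warning(flat <- classify_tci(setNames(rep(2, 5), paste0("s", 1:5))),
                 "all scores equal")
  expect_true(all(flat$phenotype == "intermediate"))

  # custom quantiles move the class fractions accordingly
  set.seed(1)
  x <- setNames(rnorm(5000), paste0("s", 1:5000))
  res2 <- classify_tci(x, lower_q = 0.30, upper_q = 0.64)
  frac <- as.vector(table(res2$phenotype)) / 5000
  expect_equal(frac, c(0.30, 0.34, 0.36), tolerance = 0.02)
})

test_that("bulk pathway scores honor signs and hand arithmetic", {
  expr <- matrix(c(2, 4, 1), nrow = 1,
                 dimnames = list("s1", c("A", "B", "C")))
  pw <- pathway_definition("P", c("A", "B", "C"), c("up", "up", "down"))
  expect_equal(pathway_score_bulk(expr, pw, signed = TRUE)$score, 5 / 3)
  expect_equal(pathway_score_bulk(expr, pw, signed = FALSE)$score, 7 / 3)

  # all-up pathway with constant value v scores v
  exprv <- matrix(3.5, nrow = 2, ncol = 3,
                  dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  pw_up <- pathway_definition("P", c("A", "B", "C"))
  expect_equal(pathway_score_bulk(exprv, pw_up, signed = TRUE)$score,
               c(3.5, 3.5))

  # flipping directions and negating expression leaves signed score fixed
  expr3 <- make_test_expr(10, c("A", "B", "C"))
  pw_flip <- pathway_definition("P", c("A", "B", "C"),
                                c("down", "down", "up"))
  expect_equal(pathway_score_bulk(-expr3, pw_flip, signed = TRUE)$score,
               pathway_score_bulk(expr3, pw, signed = TRUE)$score,
               tolerance = 1e-12)

  # matches the brute-force signed mean on random input
  expr4 <- make_test_expr(15, sprintf("G%03d", 1:12), seed = 3)
  pw4 <- pathway_definition("P", sprintf("G%03d", 1:9),
                            rep(c("up", "down", "up"), 3))
  expect_equal(pathway_score_bulk(expr4, pw4, signed = TRUE)$score,
               unname(signed_score_brute(expr4, pw4$targets$gene,
                                         pw4$targets$direction)),
               tolerance = 1e-12)
})

test_that("activation z hits its closed forms and is antisymmetric", {
  set.seed(2)
  genes <- sprintf("G%02d", 1:9)
  pw <- pathway_definition("P", genes) # all up
  base <- matrix(rnorm(8 * 9, mean = 5, sd = 0.1), nrow = 8,
                 dimnames = list(paste0("s", 1:8), genes))
  up <- base
  up[1:4, ] <- up[1:4, ] + 2 # class A higher on every target
  a <- paste0("s", 1:4); b <- paste0("s", 5:8)
  res <- activation_zscore(up, pw, a, b)
  expect_equal(res$zscore, sqrt(9))
  expect_true(res$activated)

  # half concordant / half discordant cancels exactly
  genes2 <- sprintf("H%02d", 1:4)
  m <- matrix(5, nrow = 4, ncol = 4, dimnames = list(paste0("s", 1:4), genes2))
  m[1:2, 1:2] <- 6 # two targets up in A
  m[3:4, 3:4] <- 6 # two targets down in A
  res2 <- activation_zscore(m + rnorm(16, sd = 1e-6),
                            pathway_definition("P", genes2),
                            paste0("s", 1:2), paste0("s", 3:4))
  expect_equal(res2$zscore, 0, tolerance = 1e-12)

  # swapping classes flips the sign
  res_ab <- activation_zscore(up, pw, a, b)
  res_ba <- activation_zscore(up, pw, b, a)
  expect_equal(res_ab$zscore, -res_ba$zscore)

  # |z| can never exceed sqrt(N)
  for (k in 1:10) {
    mm <- matrix(rnorm(8 * 9), nrow = 8,
                 dimnames = list(paste0("s", 1:8), genes))
    z <- activation_zscore(mm, pw, a, b)$zscore
    expect_lte(abs(z), sqrt(9) + 1e-12)
  }

  expect_error(activation_zscore(up, pw, "s1", b), "at least 2")
})

test_that("planted pathways are called activated across seeds", {
  pw <- pathway_definition("PL", sprintf("PT%02d", 1:10),
                           c(rep("up", 7), rep("down", 3)))
  hits <- vapply(1:20, function(k) {
    cfg <- synth_config(seed = k, n_tumors = 60, n_genes = 40,
                        noise_sd = 0.5, frac_inflamed = 0.5,
                        planted_pathways = list(list(pathway = pw,
                                                     delta = 2)))
    tci <- gene_signature("TCI", sprintf("TCI%03d", 1:5))
    b <- simulate_bulk_cohort(cfg, tci)
    a <- names(which(!b$truth$inflamed))
    h <- names(which(b$truth$inflamed))
    activation_zscore(b$expr, pw, a, h)$activated
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("co-occurrence regression matches exact and closed-form fits", {
  x <- 1:10
  y <- -2 * x + 10
  res <- suppressWarnings(cooccurrence_regression(tci = x, n_activated = y))
  expect_equal(res$slope, -2, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  set.seed(8)
  yr <- rnorm(1000)
  xr <- rnorm(1000)
  expect_lt(cooccurrence_regression(tci = xr, n_activated = yr)$r_squared,
            0.02)

  # 6-point table vs normal equations
  x6 <- c(0.2, 1.1, 2.3, 3.0, 4.8, 5.5)
  y6 <- c(7, 6, 6, 4, 3, 1)
  res6 <- cooccurrence_regression(tci = x6, n_activated = y6)
  oracle <- ols_brute(x6, y6)
  expect_equal(res6$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(res6$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(res6$r_squared, oracle$r_squared, tolerance = 1e-10)

  expect_error(cooccurrence_regression(tci = rep(1, 5),
                                       n_activated = 1:5),
               "zero variance")
})

test_that("pathway-signature correlations match the textbook formulas", {
  expr <- make_test_expr(50, sprintf("G%03d", 1:30), seed = 10)
  sig <- gene_signature("S", sprintf("G%03d", 1:5))
  pw_same <- pathway_definition("SAME", sprintf("G%03d", 1:5))
  pw_rand <- pathway_definition("RAND", sprintf("G%03d", 11:20))

  res <- correlate_pathways_with_tci(expr, list(pw_same, pw_rand), sig)
  expect_equal(res$r[1], 1, tolerance = 1e-12)

  tci <- tci_score(expr, sig)$score
  ps <- pathway_score_bulk(expr, pw_rand)$score
  expect_equal(res$r[2], pearson_brute(tci, ps), tolerance = 1e-12)

  res_sp <- correlate_pathways_with_tci(expr, list(pw_rand), sig,
                                        method = "spearman")
  expect_equal(res_sp$r, spearman_brute(tci, ps), tolerance = 1e-12)

  # anti-identity: pathway score = -tci score
  neg <- cbind(expr, NEG1 = -tci * 1) # one gene equal to -tci
  pw_neg <- pathway_definition("NEG", "NEG1")
  res_neg <- correlate_pathways_with_tci(neg, list(pw_neg), sig)
  expect_equal(res_neg$r, -1, tolerance = 1e-12)

  # a constant pathway yields NA with warning, others unaffected
  cst <- cbind(expr, CST = 5)
  pw_cst <- pathway_definition("CST", "CST")
  expect_warning(res_c <- correlate_pathways_with_tci(cst,
                                                      list(pw_cst, pw_rand),
                                                      sig),
                 "undefined")
  expect_true(is.na(res_c$r[1]))
  expect_equal(res_c$r[2], pearson_brute(tci, ps), tolerance = 1e-12)
})

test_that("median activation calls follow the inclusive 50% rule", {
  genes <- sprintf("G%02d", 1:12)
  # odd cohort: medians are actual sample values; engineer a 6/12 sample
  set.seed(6)
  expr <- matrix(rnorm(5 * 12), nrow = 5, dimnames = list(paste0("s", 1:5),
                                                          genes))
  pw <- pathway_definition("P", genes)
  med <- apply(expr, 2, median)
  target <- med
  target[1:6] <- med[1:6] + 1   # exactly 6 of 12 above the cohort median
  target[7:12] <- med[7:12] - 1
  expr2 <- rbind(expr, s6 = target)
  calls <- pathway_activation_call(expr2, pw)
  expect_true(calls$active[calls$sample_id == "s6"])
  expect_equal(calls$frac_up[calls$sample_id == "s6"], 0.5)

  target5 <- med
  target5[1:5] <- med[1:5] + 1
  target5[6:12] <- med[6:12] - 1
  calls5 <- pathway_activation_call(rbind(expr, s6 = target5), pw)
  expect_false(calls5$active[calls5$sample_id == "s6"])

  # identical samples: nothing is strictly above its median
  flat <- matrix(3, nrow = 4, ncol = 12,
                 dimnames = list(paste0("s", 1:4), genes))
  expect_true(all(!pathway_activation_call(flat, pw)$active))

  expect_error(pathway_activation_call(expr2[1, , drop = FALSE], pw),
               "at least 2")

  # median property: with distinct values a gene is "up" in at most
  # ceiling((n-1)/2) of n samples
  set.seed(12)
  n <- 9
  mat <- matrix(rnorm(n * 12), nrow = n,
                dimnames = list(paste0("s", 1:n), genes))
  adj_up <- sweep(mat, 2, apply(mat, 2, median), `>`)
  expect_true(all(colSums(adj_up) <= ceiling((n - 1) / 2)))
})
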
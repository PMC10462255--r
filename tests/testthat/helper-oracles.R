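# Brute-force textbook oracles, independent of the implementation paths.

bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[o][seq(i, m)] / seq(i, m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

pearson_brute <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

spearman_brute <- function(x, y) pearson_brute(rank(x), rank(y))

ols_brute <- function(x, y) {
  # normal equations for y = a + b x
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = a, slope = b, r_squared = r2)
}

km_brute <- function(time, event) {
  # product-limit over distinct event times
  ts <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

signed_score_brute <- function(mat, genes, dirs) {
  # per-row signed mean over present targets
  present <- genes %in% colnames(mat)
  genes <- genes[present]
  dirs <- dirs[present]
  s <- ifelse(dirs == "down", -1, 1)
  apply(mat, 1, function(row) mean(s * row[genes]))
}

# Small deterministic cell cohort: `per_tumor` cells per tumor, cell types
# cycled, expression standard normal unless supplied.
make_test_cohort <- function(n_tumors = 4, per_tumor = 30, genes = NULL,
                             seed = 42, types = c("malignant", "T cell",
                                                  "fibroblast")) {
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("G%03d", 1:20)
  n <- n_tumors * per_tumor
  ann <- tibble::tibble(
    cell_id = sprintf("C%04d", seq_len(n)),
    tumor_name = rep(sprintf("T%02d", seq_len(n_tumors)), each = per_tumor),
    cell_type = rep_len(types, n),
    is_malignant = rep_len(types, n) == "malignant"
  )
  vals <- matrix(rnorm(n * length(genes)), nrow = n,
                 dimnames = list(ann$cell_id, genes))
  cell_cohort(vals, ann)
}

make_test_expr <- function(n_samples = 10, genes = sprintf("G%03d", 1:20),
                           seed = 7) {
  set.seed(seed)
  matrix(rnorm(n_samples * length(genes), mean = 5), nrow = n_samples,
         dimnames = list(sprintf("S%03d", seq_len(n_samples)), genes))
}
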
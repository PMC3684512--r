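test_that("truncated correlation matches the hand-filtered worked example", {
  x <- c(2, 1, 0.5, -1, -2, 0.2)
  y <- c(2.1, 0.9, 0.6, 5, 5, 0.1)
  m <- rbind(TF = x, G = y)
  colnames(m) <- paste0("s", 1:6)
  cp <- raw_compendium(m)
  res <- truncated_correlation(cp, "TF", "G", cutoff = 0)
  # cutoff 0 keeps samples 1, 2, 3, 6
  expect_equal(res$n_used, 4L)
  expect_equal(res$r, oracle_trunc_r(x, y, 0), tolerance = 1e-12)
  expect_equal(res$r, 0.9928346592, tolerance = 1e-9)
  expect_equal(res$a, abs(res$r))
  expect_true(res$valid)
})

test_that("self-correlation is 1 and untruncated equals standard Pearson", {
  set.seed(21)
  cp <- standardize_compendium(random_matrix(20, 12))
  self <- truncated_correlation(cp, "g001", "g001", cutoff = -Inf)
  expect_equal(self$r, 1)
  expect_equal(self$a, 1)

  res <- truncated_correlation(cp, "g001", cutoff = -Inf)
  ref <- apply(cp$values, 1, function(y) cor(cp$values["g001", ], y))
  expect_equal(res$r, unname(ref), tolerance = 1e-12)
  expect_equal(res$n_used, rep(12L, 20))
})

test_that("degenerate inputs are flagged invalid, absent TF is an error", {
  x <- c(1, 2, 3, -1, -2)
  m <- rbind(TF = x, flat = c(5, 5, 5, 0, 1), g = c(1, 0, 2, 9, 9))
  colnames(m) <- paste0("s", 1:5)
  cp <- raw_compendium(m)
  # 'flat' is constant within the truncated set {1,2,3}
  res <- truncated_correlation(cp, "TF", "flat", cutoff = 0)
  expect_false(res$valid)
  expect_true(is.na(res$r) && is.na(res$a))
  # too few samples above the cutoff
  res2 <- truncated_correlation(cp, "TF", "g", cutoff = 2.5)
  expect_false(res2$valid)
  # absent gene: missing row, not an error
  res3 <- truncated_correlation(cp, "TF", c("g", "nope"), cutoff = 0)
  expect_equal(res3$valid, c(TRUE, FALSE))
  expect_error(truncated_correlation(cp, "nope"), "TF not in compendium")
  expect_error(truncated_correlation(cp, "TF", min_samples = 2),
               "min_samples")
})

test_that("batch results equal per-gene calls and match the loop oracle", {
  set.seed(31)
  cp <- standardize_compendium(random_matrix(50, 30))
  tf <- "g007"
  batch <- truncated_correlation(cp, tf, cutoff = 0.5)
  for (g in sample(rownames(cp$values), 8)) {
    single <- truncated_correlation(cp, tf, g, cutoff = 0.5)
    expect_equal(batch$r[batch$gene_id == g], single$r)
  }
  x <- cp$values[tf, ]
  for (g in rownames(cp$values)) {
    expect_equal(batch$r[batch$gene_id == g],
                 oracle_trunc_r(x, cp$values[g, ], 0.5),
                 tolerance = 1e-12)
  }
})

test_that("valid correlations stay in bounds and |r| ignores sign flips", {
  set.seed(41)
  for (rep in 1:20) {
    cp <- standardize_compendium(random_matrix(15, 10))
    cc <- sample(c(-Inf, -1, 0, 1), 1)
    res <- truncated_correlation(cp, "g001", cutoff = cc)
    ok <- res$valid
    expect_true(all(res$r[ok] >= -1 & res$r[ok] <= 1))
    expect_true(all(res$a[ok] >= 0 & res$a[ok] <= 1))
    flipped <- cp
    flipped$values[2, ] <- -flipped$values[2, ]
    res_f <- truncated_correlation(flipped, "g001", cutoff = cc)
    expect_equal(res_f$a[2], res$a[2])
    expect_equal(res_f$r[2], -res$r[2])
  }
})

test_that("the truncated sample count never grows with the cutoff", {
  set.seed(51)
  cp <- standardize_compendium(random_matrix(5, 40))
  cuts <- c(-Inf, -2, -1, 0, 1, 2)
  n_used <- sapply(cuts, function(cc)
    truncated_correlation(cp, "g001", "g002", cutoff = cc)$n_used)
  expect_true(all(diff(n_used) <= 0))
  expect_equal(n_used[1], 40L)
})

test_that("z-scores are referenced to the all-gene null distribution", {
  set.seed(61)
  raw <- random_matrix(100, 40)
  raw[2, ] <- raw[1, ] + rnorm(40, sd = 0.1)  # planted target of g001
  cp <- standardize_compendium(raw)
  all_res <- truncated_correlation(cp, "g001", cutoff = 0)
  null_r <- all_res$r[all_res$valid]
  z <- correlation_zscore(cp, "g001", "g002", cutoff = 0)
  expect_equal(z, (all_res$r[2] - mean(null_r)) / sd(null_r),
               tolerance = 1e-12)
  # the planted target has the largest z among non-TF genes
  zs <- (all_res$r - mean(null_r)) / sd(null_r)
  expect_equal(which.max(zs[-1]) + 1L, 2L)

  # z is centered on the null: a gene whose r equals the null mean scores 0,
  # so the z-scores of the null genes themselves average to exactly 0
  expect_lt(abs(mean(zs[all_res$valid])), 1e-10)
})

test_that("z-score degenerate cases error out", {
  small <- raw_compendium(random_matrix(5, 10))
  expect_error(correlation_zscore(small, "g001", "g002"),
               "null distribution too small")
  # identical rows give a constant null
  m <- matrix(rep(c(1, 2, 3, 0, -1, -2, 0.5, 1.5, -0.5, 2.5), each = 12),
              nrow = 12, byrow = FALSE,
              dimnames = list(sprintf("g%03d", 1:12), sprintf("s%02d", 1:10)))
  cp <- raw_compendium(m)
  expect_error(correlation_zscore(cp, "g001", "g002"),
               "degenerate null|identical")
})

test_that("TF low-expression diagnostics use two-tier quantile warnings", {
  set.seed(71)
  n <- 100
  m <- random_matrix(n, 10)
  m <- m * seq(0.5, 2, length.out = n)  # spread of variances
  m <- m + seq_len(n)                   # spread of means
  cp <- standardize_compendium(m)
  meta <- cp$gene_meta

  # TF with the smallest variance -> strong variance warning
  tf_minvar <- meta$gene_id[which.min(meta$var)]
  d <- tf_diagnostics(cp, tf_minvar)
  expect_equal(d$warning[d$statistic == "var"], "strong")

  # TF at the median of a statistic -> no warning for it
  tf_med <- meta$gene_id[order(meta$mean)][n / 2]
  d2 <- tf_diagnostics(cp, tf_med)
  expect_equal(d2$warning[d2$statistic == "mean"], "none")

  # TF at the 10th percentile of means -> mild (below 25th, not 5th)
  tf_p10 <- meta$gene_id[order(meta$mean)][11]
  d3 <- tf_diagnostics(cp, tf_p10)
  expect_equal(d3$warning[d3$statistic == "mean"], "mild")

  expect_true(all(d$quantile_position >= 0 & d$quantile_position <= 1))
  expect_error(tf_diagnostics(cp, "absent"), "TF not in compendium")
})
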
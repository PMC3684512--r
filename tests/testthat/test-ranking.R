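# helper: compendium in which gene correlations with the TF are controlled
# by construction (gene = coupling * TF + noise)
coupled_compendium <- function(couplings, n_samples = 60) {
  x <- stats::rnorm(n_samples)
  rows <- lapply(couplings, function(b)
    b * x + sqrt(max(0, 1 - b^2)) * stats::rnorm(n_samples))
  m <- do.call(rbind, c(list(x), rows))
  rownames(m) <- c("TF", names(couplings))
  colnames(m) <- sprintf("s%03d", seq_len(n_samples))
  standardize_compendium(m)
}

test_that("expression-only ranking puts the TF first and orders by |r|", {
  set.seed(19)
  cp <- coupled_compendium(c(gHI = 0.9, gLO = 0.3, gMD = 0.6))
  out <- geo_only_rank(cp, "TF", cutoff = -Inf)
  expect_equal(out$gene_id[1], "TF")  # self-correlation 1 beats everything
  expect_equal(out$A, 1:4)
  ranks <- match(c("gHI", "gMD", "gLO"), out$gene_id)
  expect_true(all(diff(ranks) > 0))
  expect_error(geo_only_rank(cp, "nope"), "TF not in compendium")
})

test_that("invalid correlations rank after all valid genes", {
  set.seed(23)
  m <- random_matrix(6, 10)
  m["g003", ] <- 4  # constant: invalid everywhere
  cp <- standardize_compendium(m)
  out <- geo_only_rank(cp, "g001", cutoff = 0)
  expect_equal(out$gene_id[nrow(out)], "g003")
  expect_false(out$valid[nrow(out)])

  bound <- data.frame(gene_id = c("g002", "g003", "g004"), P = 1:3)
  fit <- tfrank(bound, cp, "g001")
  expect_equal(fit$ranking$A[fit$ranking$gene_id == "g003"], 3L)
})

test_that("the fused score is the stated linear combination of ranks", {
  set.seed(29)
  # couplings chosen so |r| orders g2 > g3 > g1, i.e. A = (3, 1, 2)
  cp <- coupled_compendium(c(g1 = 0.1, g2 = 0.95, g3 = 0.6), n_samples = 200)
  bound <- data.frame(gene_id = c("g1", "g2", "g3"), P = 1:3)
  fit <- tfrank(bound, cp, "TF", cutoff = -Inf, weight = 0.1)
  r <- fit$ranking
  expect_equal(r$A[match(c("g1", "g2", "g3"), r$gene_id)], c(3L, 1L, 2L))
  expect_equal(r$R[match(c("g1", "g2", "g3"), r$gene_id)], c(2.8, 1.1, 2.1))
  expect_equal(r$gene_id, c("g2", "g3", "g1"))
  expect_true(all(r$R >= 1 & r$R <= nrow(r)))
})

test_that("w = 1 reproduces the ChIP-only order, w = 0 the |r| order", {
  set.seed(37)
  for (rep in 1:10) {
    cp <- standardize_compendium(random_matrix(40, 25))
    ids <- sample(rownames(cp$values), 15)
    bound <- data.frame(gene_id = ids, P = sample.int(15))
    chip_order <- bound$gene_id[order(bound$P)]

    w1 <- tfrank(bound, cp, "g001", weight = 1)
    expect_equal(w1$ranking$gene_id, chip_order)

    w0 <- tfrank(bound, cp, "g001", weight = 0)
    cors <- truncated_correlation(cp, "g001", chip_order)
    a_order <- chip_order[order(-cors$a, seq_along(chip_order))]
    expect_equal(w0$ranking$gene_id, a_order)
  }
})

test_that("bound genes missing from the compendium are reported unranked", {
  set.seed(43)
  cp <- standardize_compendium(random_matrix(10, 8))
  bound <- data.frame(gene_id = c("g002", "ghost", "g005"), P = 1:3)
  fit <- tfrank(bound, cp, "g001")
  expect_equal(fit$unranked, "ghost")
  expect_false("ghost" %in% fit$ranking$gene_id)
  # P re-ranked over the remaining set
  expect_equal(sort(fit$ranking$P), 1:2)
})

test_that("input order of the bound list does not affect the result", {
  set.seed(47)
  cp <- standardize_compendium(random_matrix(30, 20))
  ids <- sample(rownames(cp$values), 12)
  bound <- data.frame(gene_id = ids, P = sample.int(12))
  fit1 <- tfrank(bound, cp, "g001")
  perm <- sample.int(12)
  fit2 <- tfrank(bound[perm, ], cp, "g001")
  expect_equal(fit1$ranking, fit2$ranking)
})

test_that("improving a gene's correlation rank never demotes it", {
  set.seed(53)
  cp <- coupled_compendium(c(gA = 0.2, gB = 0.5, gC = 0.8), n_samples = 100)
  bound <- data.frame(gene_id = c("gA", "gB", "gC"), P = 1:3)
  before <- tfrank(bound, cp, "TF", cutoff = -Inf)
  pos_before <- match("gA", before$ranking$gene_id)
  # strengthen gA's coupling far above the rest
  cp$values["gA", ] <- cp$values["TF", ] * 0.99 +
    0.01 * cp$values["gA", ]
  after <- tfrank(bound, cp, "TF", cutoff = -Inf)
  expect_lte(match("gA", after$ranking$gene_id), pos_before)
})

test_that("parameter validation and output files behave", {
  set.seed(59)
  cp <- standardize_compendium(random_matrix(10, 8))
  bound <- data.frame(gene_id = c("g002", "g003"), P = 1:2)
  expect_error(tfrank(bound, cp, "g001", weight = 1.2), "weight")
  expect_error(tfrank(bound, cp, "absent"), "TF not in compendium")
  expect_error(tfrank(bound[0, ], cp, "g001"), "no bound genes")

  fit <- tfrank(bound, cp, "g001")
  path <- file.path(tempdir(), "ranked.tsv")
  write_tfrank(fit, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$gene_id, fit$ranking$gene_id)
  expect_true(file.exists(paste0(path, ".unranked.txt")))
})
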
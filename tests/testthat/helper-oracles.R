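# Independent oracles and small fixture builders, kept deliberately naive
# so they share no code path with the package internals.

# Pearson correlation on the manually filtered truncated sample set.
oracle_trunc_r <- function(x, y, cutoff, min_samples = 3L) {
  keep <- which(x >= cutoff)
  if (length(keep) < min_samples) return(NA_real_)
  xs <- x[keep]; ys <- y[keep]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

# Exhaustive strand-aware peak-to-gene scan, O(peaks x genes).
oracle_bound_genes <- function(peaks, annotation, upstream = 10000L,
                               downstream = 5000L, mode = "center") {
  best <- numeric(0)
  for (i in seq_len(nrow(annotation))) {
    g <- annotation$gene_id[i]
    if (annotation$strand[i] == "+") {
      lo <- annotation$tss[i] - upstream
      hi <- annotation$tss[i] + downstream
    } else {
      lo <- annotation$tss[i] - downstream
      hi <- annotation$tss[i] + upstream
    }
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != annotation$chrom[i]) next
      hit <- if (mode == "center") {
        mid <- floor((peaks$start[j] + peaks$end[j]) / 2)
        mid >= lo && mid <= hi
      } else {
        peaks$start[j] <= hi && (peaks$end[j] - 1L) >= lo
      }
      if (hit && (is.na(best[g]) || peaks$rank[j] < best[g]))
        best[g] <- peaks$rank[j]
    }
  }
  best <- best[!is.na(best)]
  if (length(best) == 0L)
    return(data.frame(gene_id = character(0), P = integer(0),
                      best_peak_rank = integer(0)))
  ord <- order(best, names(best))
  data.frame(gene_id = names(best)[ord], P = seq_along(ord),
             best_peak_rank = unname(best[ord]), row.names = NULL,
             stringsAsFactors = FALSE)
}

# fraction of top-k genes in the gold set, counted one by one
oracle_ppv <- function(ranked, gold, k) {
  sum(vapply(seq_len(k), function(i) ranked[i] %in% gold, logical(1))) / k
}

# compendium wrapper over a raw matrix without standardizing (for tests
# that need exact hand-picked expression values)
raw_compendium <- function(values) {
  tfrank::expression_compendium(values)
}

# random gene x sample matrix with IDs
random_matrix <- function(n_genes, n_samples, gene_prefix = "g") {
  matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("%s%03d", gene_prefix, seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# random genomics instance: peaks + multi-TSS annotation on few chromosomes
random_genomics_instance <- function(n_peaks, n_genes) {
  chroms <- c("chr1", "chr2", "chr3")
  # a few genes get alternative-TSS records
  extra <- sample(n_genes, max(1, n_genes %/% 5))
  ann <- data.frame(
    gene_id = sprintf("g%03d", c(seq_len(n_genes), extra)),
    chrom = sample(chroms, n_genes + length(extra), replace = TRUE),
    strand = sample(c("+", "-"), n_genes + length(extra), replace = TRUE),
    tss = sample.int(200000L, n_genes + length(extra)),
    stringsAsFactors = FALSE)
  width <- sample(50:2000, n_peaks, replace = TRUE)
  start <- sample.int(200000L, n_peaks)
  peaks <- data.frame(chrom = sample(chroms, n_peaks, replace = TRUE),
                      start = start, end = start + width,
                      rank = sample.int(n_peaks),
                      stringsAsFactors = FALSE)
  list(peaks = peaks, annotation = ann)
}
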
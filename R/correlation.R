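# Truncated Pearson correlation between a TF and compendium genes,
# null-based z-scores, and TF low-expression diagnostics.

#' Truncated absolute correlation between a TF and genes
#'
#' The truncated Pearson correlation between a transcription factor t and a
#' gene g is the ordinary Pearson correlation computed only over the sample
#' set `C = { i : x_ti >= cutoff }`, where `x_ti` is the TF's standardized
#' expression in sample i. Restricting to samples where the TF is expressed
#' at or above `cutoff` discards samples in which a target gene may be
#' driven by other regulators while the TF is off, which dilutes the global
#' correlation. The truncated absolute correlation `a = |r|` measures
#' regulatory strength for activated and repressed targets alike. With
#' `cutoff = -Inf` the measure reduces exactly to the standard Pearson
#' correlation over all samples.
#'
#' @param cp an [expression_compendium()]; `cutoff` is interpreted on the
#'   standardized scale, so the default 0 selects samples where the TF is at
#'   or above its compendium-wide average.
#' @param tf_id gene ID of the TF of interest; must be in the compendium.
#' @param gene_ids character vector of genes to correlate with the TF;
#'   defaults to every gene in the compendium. Genes absent from the
#'   compendium yield a missing (invalid) row rather than an error.
#' @param cutoff truncation cutoff c, in standardized expression units
#'   (default 0; `-Inf` disables truncation).
#' @param min_samples minimum size of the truncated sample set for a
#'   correlation to be considered valid (default 3; must be >= 3).
#' @return A data frame with one row per requested gene, in input order:
#'   `gene_id`, `r` (truncated Pearson correlation), `a` (`|r|`), `n_used`
#'   (size of the truncated sample set) and `valid`. A result is invalid —
#'   with `r` and `a` set to `NA` — when fewer than `min_samples` samples
#'   survive truncation, when either variable is constant within the
#'   truncated set, or when the gene is absent from the compendium.
#' @export
truncated_correlation <- function(cp, tf_id, gene_ids = NULL, cutoff = 0,
                                  min_samples = 3L) {
  stopifnot(inherits(cp, "expression_compendium"))
  if (length(tf_id) != 1L || !tf_id %in% rownames(cp$values))
    stop("TF not in compendium: ", tf_id)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff))
    stop("'cutoff' must be a single number (or -Inf)")
  min_samples <- as.integer(min_samples)
  if (min_samples < 3L) stop("'min_samples' must be >= 3")
  if (is.null(gene_ids)) gene_ids <- rownames(cp$values)
  gene_ids <- as.character(gene_ids)

  x <- cp$values[tf_id, ]
  keep <- which(x >= cutoff)
  n_used <- length(keep)

  out <- data.frame(gene_id = gene_ids, r = NA_real_, a = NA_real_,
                    n_used = n_used, valid = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  present <- gene_ids %in% rownames(cp$values)
  if (n_used >= min_samples && any(present)) {
    xs <- x[keep]
    xc <- xs - mean(xs)
    ssx <- sum(xc^2)
    if (ssx > 0) {
      Y <- cp$values[gene_ids[present], keep, drop = FALSE]
      Yc <- Y - rowMeans(Y)
      ssy <- rowSums(Yc^2)
      num <- as.vector(Yc %*% xc)
      ok <- ssy > 0
      r <- rep(NA_real_, nrow(Y))
      r[ok] <- num[ok] / sqrt(ssx * ssy[ok])
      # clamp fp overshoot just outside [-1, 1]
      r[ok] <- pmin(1, pmax(-1, r[ok]))
      out$r[present] <- r
      out$a[present] <- abs(r)
      out$valid[present] <- ok
    }
  }
  out
}

#' Null-referenced z-score of a truncated correlation
#'
#' The truncated correlations between the TF and every valid gene in the
#' compendium (the TF itself included, contributing its self-correlation of
#' 1) form an empirical null distribution. The z-score of a gene's truncated
#' correlation is its distance from the null mean in null standard
#' deviations, which quantifies how well it separates from the bulk of the
#' compendium.
#'
#' @inheritParams truncated_correlation
#' @param gene_id single gene whose correlation is to be scored.
#' @return A single number, `(r - mean(null)) / sd(null)`.
#' @export
correlation_zscore <- function(cp, tf_id, gene_id, cutoff = 0,
                               min_samples = 3L) {
  all_res <- truncated_correlation(cp, tf_id, cutoff = cutoff,
                                   min_samples = min_samples)
  null_r <- all_res$r[all_res$valid]
  if (length(null_r) < 10L)
    stop("null distribution too small (", length(null_r), " valid genes)")
  s <- stats::sd(null_r)
  if (s == 0) stop("degenerate null distribution: all correlations identical")
  row <- all_res[match(gene_id, all_res$gene_id), ]
  if (is.na(row$gene_id[1L])) {
    row <- truncated_correlation(cp, tf_id, gene_id, cutoff = cutoff,
                                 min_samples = min_samples)
  }
  if (!isTRUE(row$valid[1L]))
    stop("no valid truncated correlation for gene ", gene_id)
  (row$r[1L] - mean(null_r)) / s
}

#' Low-expression diagnostics for the TF of interest
#'
#' A TF that is expressed at consistently low levels, or varies little,
#' across the compendium gives weakly informative correlations. Each of the
#' TF's pre-standardization mean, variance and coefficient of variation is
#' located within the corresponding all-gene distribution; a statistic below
#' the 25th percentile draws a mild warning and below the 5th percentile a
#' strong one.
#'
#' @inheritParams truncated_correlation
#' @return An object of class `tf_diagnostics`: a data frame with rows
#'   `mean`, `var`, `cv` and columns `value`, `quantile_position` (fraction
#'   of genes strictly below the TF's value) and `warning` (one of `none`,
#'   `mild`, `strong`).
#' @export
tf_diagnostics <- function(cp, tf_id) {
  stopifnot(inherits(cp, "expression_compendium"))
  meta <- cp$gene_meta
  i <- match(tf_id, meta$gene_id)
  if (is.na(i)) stop("TF not in compendium: ", tf_id)
  stat_names <- c("mean", "var", "cv")
  qpos <- vapply(stat_names, function(s) {
    mean(meta[[s]] < meta[[s]][i])
  }, numeric(1))
  level <- ifelse(qpos < 0.05, "strong", ifelse(qpos < 0.25, "mild", "none"))
  out <- data.frame(statistic = stat_names,
                    value = c(meta$mean[i], meta$var[i], meta$cv[i]),
                    quantile_position = unname(qpos),
                    warning = unname(level),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tf_id") <- tf_id
  class(out) <- c("tf_diagnostics", "data.frame")
  out
}

#' @export
print.tf_diagnostics <- function(x, ...) {
  cat("TF expression diagnostics for", attr(x, "tf_id"), "\n")
  print.data.frame(x, ...)
  if (any(x$warning != "none"))
    cat("warning: TF expression statistics fall in the low tail of the",
        "all-gene distribution;\ncorrelation-based ranking may be",
        "uninformative for this TF\n")
  invisible(x)
}
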
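# Gold standards, PPV curves, normalized AUC, and the three-method
# comparison harness.

#' Build a gold standard of functional target genes
#'
#' Functional targets are genes both bound by the TF (ChIP evidence) and
#' differentially expressed under TF perturbation. The gold standard is the
#' intersection of the two gene sets.
#'
#' @param bound_genes character vector of bound gene IDs.
#' @param de_genes character vector of differentially expressed gene IDs
#'   (same ID namespace).
#' @return Character vector of gold-standard gene IDs (sorted). Empty with a
#'   warning if the sets are disjoint.
#' @export
make_gold_standard <- function(bound_genes, de_genes) {
  gold <- sort(intersect(as.character(bound_genes), as.character(de_genes)))
  if (length(gold) == 0L)
    warning("bound and differentially-expressed gene sets are disjoint; ",
            "empty gold standard")
  gold
}

#' Positive-predictive-value curve of a ranking
#'
#' `ppv(k)` is the fraction of the top k ranked genes that belong to the
#' gold standard.
#'
#' @param ranked_genes character vector of gene IDs, best first.
#' @param gold character vector of gold-standard gene IDs.
#' @param list_sizes increasing integer vector of list sizes k; defaults to
#'   `1:length(ranked_genes)`. Sizes beyond the ranking length are dropped
#'   with a warning.
#' @return A data frame `k`, `ppv`.
#' @export
ppv_curve <- function(ranked_genes, gold, list_sizes = NULL) {
  ranked_genes <- as.character(ranked_genes)
  if (length(ranked_genes) == 0L) stop("empty ranking")
  if (is.null(list_sizes)) list_sizes <- seq_along(ranked_genes)
  list_sizes <- as.integer(list_sizes)
  if (any(list_sizes < 1L)) stop("list sizes must be >= 1")
  over <- list_sizes > length(ranked_genes)
  if (any(over)) {
    warning("list sizes beyond ranking length dropped")
    list_sizes <- list_sizes[!over]
  }
  hits <- cumsum(ranked_genes %in% gold)
  data.frame(k = list_sizes, ppv = hits[list_sizes] / list_sizes)
}

#' Normalized area under the PPV curve
#'
#' The area under the PPV curve over list sizes 1..n divided by the total
#' plot area, which equals the mean PPV over those list sizes:
#' \deqn{nAUC(n) = \frac{1}{n} \sum_{k=1}^{n} ppv(k).}
#'
#' @inheritParams ppv_curve
#' @param n evaluation horizon; must not exceed the ranking length.
#' @return A single number in \[0, 1\].
#' @export
nauc <- function(ranked_genes, gold, n) {
  ranked_genes <- as.character(ranked_genes)
  if (length(ranked_genes) == 0L) stop("empty ranking")
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("'n' must be >= 1")
  if (n > length(ranked_genes))
    stop("'n' exceeds ranking length (", length(ranked_genes), ")")
  k <- seq_len(n)
  hits <- cumsum(ranked_genes[k] %in% gold)
  mean(hits / k)
}

#' Compare ChIP-only, expression-only and fused rankings by nAUC
#'
#' Evaluates the three ranking strategies against a gold standard over a
#' grid of truncation cutoffs and fusion weights. For a fair comparison,
#' all methods are primarily evaluated on the shared gene universe of bound
#' genes present in the compendium (`universe = "bound_in_compendium"`);
#' the expression-only ranking is additionally reported over the full
#' compendium (`universe = "compendium"`), which is how it is defined when
#' no binding information is used at all.
#'
#' @param bound a bound-gene ranking (see [tfrank()]).
#' @inheritParams tfrank
#' @param gold gold-standard gene IDs.
#' @param cutoffs numeric vector of truncation cutoffs for the fused and
#'   expression-only methods (default 0; `-Inf` = no truncation).
#' @param weights numeric vector of fusion weights (default 0.1).
#' @param n integer vector of evaluation horizons (default 100).
#' @param dataset label copied into the output (default `"dataset"`).
#' @return A long-format data frame: `dataset`, `method` (`"chip_only"`,
#'   `"expression_only"`, `"fused"`), `cutoff`, `weight`, `universe`, `n`,
#'   `nauc`. For `"chip_only"`, `cutoff` and `weight` are `NA`; rows with
#'   `weight = 1` reproduce the ChIP-only nAUC exactly.
#' @export
compare_methods <- function(bound, cp, tf_id, gold, cutoffs = 0,
                            weights = 0.1, n = 100L, min_samples = 3L,
                            dataset = "dataset") {
  stopifnot(length(cutoffs) > 0L, length(weights) > 0L, length(n) > 0L)
  rows <- list()
  add <- function(method, cutoff, weight, universe, horizon, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      dataset = dataset, method = method, cutoff = cutoff, weight = weight,
      universe = universe, n = horizon, nauc = value,
      stringsAsFactors = FALSE)
  }

  # shared universe: bound genes present in the compendium, ChIP order
  bound <- as.data.frame(bound)
  in_cp <- bound$gene_id %in% rownames(cp$values)
  shared <- bound[in_cp, , drop = FALSE]
  shared <- shared$gene_id[order(shared$P)]
  clip <- function(h, len) min(h, len)

  for (h in n) {
    add("chip_only", NA_real_, NA_real_, "bound_in_compendium", h,
        nauc(shared, gold, clip(h, length(shared))))
  }
  for (cc in cutoffs) {
    geo_restricted <- tfrank(bound, cp, tf_id, cutoff = cc, weight = 0,
                             min_samples = min_samples)$ranking$gene_id
    geo_full <- geo_only_rank(cp, tf_id, cutoff = cc,
                              min_samples = min_samples)$gene_id
    for (h in n) {
      add("expression_only", cc, NA_real_, "bound_in_compendium", h,
          nauc(geo_restricted, gold, clip(h, length(geo_restricted))))
      add("expression_only", cc, NA_real_, "compendium", h,
          nauc(geo_full, gold, clip(h, length(geo_full))))
    }
    for (w in weights) {
      fused <- tfrank(bound, cp, tf_id, cutoff = cc, weight = w,
                      min_samples = min_samples)$ranking$gene_id
      for (h in n) {
        add("fused", cc, w, "bound_in_compendium", h,
            nauc(fused, gold, clip(h, length(fused))))
      }
    }
  }
  do.call(rbind, rows)
}
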
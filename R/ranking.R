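# Fused ranking of TF-bound genes: R = w * P + (1 - w) * A.

#' Rank all compendium genes by truncated absolute correlation
#'
#' The expression-only ("GEO-only") ranking: every gene in the compendium is
#' ranked by its truncated absolute correlation `a` with the TF, largest
#' first. Genes whose correlation is invalid (too few samples after
#' truncation, or zero variance) are placed after all valid genes, ordered
#' by gene ID.
#'
#' @inheritParams truncated_correlation
#' @return A data frame ordered by rank: `gene_id`, `A` (rank, 1 = largest
#'   `a`), `r`, `a`, `n_used`, `valid`.
#' @export
geo_only_rank <- function(cp, tf_id, cutoff = 0, min_samples = 3L) {
  res <- truncated_correlation(cp, tf_id, cutoff = cutoff,
                               min_samples = min_samples)
  ord <- order(!res$valid, -ifelse(res$valid, res$a, -Inf), res$gene_id)
  out <- res[ord, c("gene_id", "r", "a", "n_used", "valid")]
  out <- data.frame(gene_id = out$gene_id, A = seq_len(nrow(out)),
                    r = out$r, a = out$a, n_used = out$n_used,
                    valid = out$valid, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Fuse ChIP binding ranks with compendium correlation ranks
#'
#' The central estimator of the package. Bound genes carrying a ChIP-only
#' rank are re-ranked by the fused score
#' \deqn{R_g = w P_g + (1 - w) A_g,}
#' where `P_g` is the ChIP-only rank (from peak strength), `A_g` is the rank
#' of the truncated absolute correlation `a` between the TF and gene `g`
#' across the expression compendium, and `w` in \[0, 1\] weights the two
#' sources. Smaller `R` is better. With `w = 1` the fused order reduces to
#' the ChIP-only order; with `w = 0` it reduces to ranking the bound genes
#' by `a` alone.
#'
#' Bound genes with no expression measurement in the compendium cannot be
#' scored and are reported separately as `unranked`. Both `P` and `A` are
#' ranks over the remaining set of size G', so the two scales are
#' commensurate: `P` is re-ranked to `1..G'` preserving the ChIP order, and
#' `A` assigns `1..G'` by decreasing `a` (ties broken by smaller `P`, then
#' gene ID; invalid correlations come last, ordered by gene ID).
#'
#' @param bound a [peaks_to_bound_genes()] result, or any data frame with
#'   columns `gene_id` and `P` (unique ChIP-only ranks).
#' @inheritParams truncated_correlation
#' @param weight fusion weight `w` in \[0, 1\] (default 0.1).
#' @param exclude_tf drop the TF itself from the ranking (its
#'   self-correlation of 1 otherwise keeps it near the top when it is bound;
#'   default `FALSE`).
#' @return An object of class `tfrank`: a list with elements `ranking`
#'   (data frame `gene_id`, `R`, `P`, `A`, `a`, `n_used`, sorted by `R`
#'   ascending, ties by smaller `P` then gene ID), `unranked` (bound genes
#'   absent from the compendium), `tf_id` and `params`.
#' @seealso [geo_only_rank()], [peaks_to_bound_genes()], [ppv_curve()]
#' @examples
#' set.seed(1)
#' raw <- matrix(rnorm(50 * 20), 50, 20,
#'               dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:20)))
#' raw[2, ] <- raw[1, ] * 0.8 + rnorm(20, sd = 0.4)  # g02 tracks the TF g01
#' cp <- standardize_compendium(raw)
#' bound <- data.frame(gene_id = c("g02", "g07", "g11"), P = 1:3)
#' fit <- tfrank(bound, cp, tf_id = "g01")
#' fit
#' @export
tfrank <- function(bound, cp, tf_id, cutoff = 0, weight = 0.1,
                   min_samples = 3L, exclude_tf = FALSE) {
  stopifnot(inherits(cp, "expression_compendium"))
  bound <- as.data.frame(bound)
  if (nrow(bound) == 0L) stop("no bound genes")
  if (!all(c("gene_id", "P") %in% names(bound)))
    stop("'bound' needs columns gene_id and P")
  if (anyDuplicated(bound$gene_id))
    stop("duplicate gene_id in bound list")
  if (anyDuplicated(bound$P))
    stop("ChIP-only ranks P must be unique")
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0 || weight > 1)
    stop("'weight' must be in [0, 1]")
  if (!tf_id %in% rownames(cp$values))
    stop("TF not in compendium: ", tf_id)

  if (exclude_tf) bound <- bound[bound$gene_id != tf_id, , drop = FALSE]

  in_cp <- bound$gene_id %in% rownames(cp$values)
  unranked <- sort(bound$gene_id[!in_cp])
  ranked <- bound[in_cp, , drop = FALSE]
  if (nrow(ranked) == 0L)
    stop("no bound gene has an expression measurement in the compendium")

  # re-rank P over the retained set, preserving the ChIP order
  ranked <- ranked[order(ranked$P), , drop = FALSE]
  P <- seq_len(nrow(ranked))

  cors <- truncated_correlation(cp, tf_id, ranked$gene_id, cutoff = cutoff,
                                min_samples = min_samples)
  # A: a descending; ties by smaller P, then gene_id; invalid last by gene_id
  a_key <- ifelse(cors$valid, cors$a, -Inf)
  ordA <- order(-a_key, ifelse(cors$valid, P, 0L), ranked$gene_id)
  A <- integer(nrow(ranked))
  A[ordA] <- seq_len(nrow(ranked))

  R <- weight * P + (1 - weight) * A
  tab <- data.frame(gene_id = ranked$gene_id, R = R, P = P, A = A,
                    a = cors$a, n_used = cors$n_used, row.names = NULL,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$R, tab$P, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL

  structure(list(ranking = tab, unranked = unranked, tf_id = tf_id,
                 params = list(cutoff = cutoff, weight = weight,
                               min_samples = as.integer(min_samples))),
            class = "tfrank")
}

#' @export
print.tfrank <- function(x, n = 10L, ...) {
  cat("Fused bound-gene ranking for TF", x$tf_id,
      sprintf("(cutoff = %g, weight = %g)\n", x$params$cutoff,
              x$params$weight))
  cat(nrow(x$ranking), "genes ranked;", length(x$unranked),
      "bound genes absent from the compendium\n")
  print.data.frame(utils::head(x$ranking, n), digits = 4, ...)
  if (nrow(x$ranking) > n) cat("...", nrow(x$ranking) - n, "more\n")
  invisible(x)
}

#' @export
summary.tfrank <- function(object, ...) {
  r <- object$ranking
  cat("Fused bound-gene ranking for TF", object$tf_id, "\n")
  cat(sprintf("  cutoff c = %g, weight w = %g\n", object$params$cutoff,
              object$params$weight))
  cat("  ranked genes:   ", nrow(r), "\n")
  cat("  unranked genes: ", length(object$unranked),
      "(no expression measurement)\n")
  ok <- !is.na(r$a)
  cat("  valid correlations:", sum(ok), "of", nrow(r), "\n")
  if (any(ok))
    cat(sprintf("  truncated |r|: median %.3f, max %.3f (n_used = %d)\n",
                stats::median(r$a[ok]), max(r$a[ok]), r$n_used[1L]))
  invisible(object)
}

#' @export
as.data.frame.tfrank <- function(x, ...) x$ranking

#' Plot a fused ranking
#'
#' Without a gold standard, plots the truncated absolute correlation `a`
#' against the ChIP-only rank `P`, the two sources of evidence the fused
#' score combines. With a gold standard, draws the PPV curve of the fused
#' ranking (see [ppv_curve()]).
#'
#' @param x a `tfrank` object.
#' @param gold optional character vector of gold-standard gene IDs.
#' @param ... passed to the underlying plot call.
#' @export
plot.tfrank <- function(x, gold = NULL, ...) {
  r <- x$ranking
  if (is.null(gold)) {
    graphics::plot(r$P, r$a, xlab = "ChIP-only rank P",
                   ylab = "truncated |r|",
                   main = paste("Evidence for TF", x$tf_id), ...)
  } else {
    pc <- ppv_curve(r$gene_id, gold)
    graphics::plot(pc$k, pc$ppv, type = "l", ylim = c(0, 1),
                   xlab = "top-k list size", ylab = "PPV",
                   main = paste("PPV of fused ranking, TF", x$tf_id), ...)
  }
  invisible(x)
}

#' Write a fused ranking to disk
#'
#' Writes `<path>` as a TSV (`rank`, `gene_id`, `R`, `P`, `A`, `a`,
#' `n_used`) and `<path>.unranked.txt` listing bound genes that had no
#' expression measurement, one per line.
#'
#' @param x a `tfrank` object.
#' @param path output TSV path.
#' @return Invisibly, the paths written.
#' @export
write_tfrank <- function(x, path) {
  stopifnot(inherits(x, "tfrank"))
  tab <- cbind(rank = seq_len(nrow(x$ranking)), x$ranking)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  up <- paste0(path, ".unranked.txt")
  writeLines(x$unranked, up)
  invisible(c(path, up))
}
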
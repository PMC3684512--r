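# Expression compendium: build, standardize, read, write.

#' Construct an expression compendium object
#'
#' Low-level constructor. Most users build compendia with
#' [standardize_compendium()] or read them with [read_compendium()].
#'
#' @param values numeric matrix, genes x samples, with unique rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param gene_meta data frame with one row per gene and columns
#'   `gene_id`, `mean`, `var`, `cv`, `zero_variance`, giving the
#'   pre-standardization statistics of each gene. If `NULL`, the entries are
#'   computed from `values` (only correct when `values` is not yet
#'   standardized).
#' @return An object of class `expression_compendium`: a list with elements
#'   `values` and `gene_meta`.
#' @export
expression_compendium <- function(values, gene_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene_id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_id")
  if (!all(is.finite(values)))
    stop("non-finite values in expression matrix")
  if (ncol(values) < 2L)
    stop("a compendium needs at least 2 samples")
  if (is.null(gene_meta)) {
    gene_meta <- gene_row_stats(values)
  } else {
    gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
    need <- c("gene_id", "mean", "var", "cv", "zero_variance")
    if (!all(need %in% names(gene_meta)))
      stop("gene_meta must have columns: ", paste(need, collapse = ", "))
    if (!identical(as.character(gene_meta$gene_id), rownames(values)))
      stop("gene_meta rows must match rownames(values) in order")
  }
  structure(list(values = values, gene_meta = gene_meta),
            class = "expression_compendium")
}

# Pre-standardization per-gene statistics. Sample variance (n - 1).
# cv = sd/mean; constant rows get cv = 0; mean 0 with spread gets +Inf.
gene_row_stats <- function(values) {
  mu <- rowMeans(values)
  v <- rowSums((values - mu)^2) / (ncol(values) - 1L)
  s <- sqrt(v)
  zero_var <- s == 0
  cv <- ifelse(zero_var, 0, ifelse(mu == 0, Inf, s / mu))
  data.frame(gene_id = rownames(values), mean = mu, var = v, cv = cv,
             zero_variance = zero_var, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat("Expression compendium:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  nz <- sum(x$gene_meta$zero_variance)
  if (nz > 0) cat("  zero-variance genes:", nz, "\n")
  invisible(x)
}

#' @export
dim.expression_compendium <- function(x) dim(x$values)

#' Gene and sample identifiers of a compendium
#' @param cp an `expression_compendium`.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(cp) rownames(cp$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(cp) colnames(cp$values)

#' Collapse a probeset-level matrix to gene level
#'
#' Microarray platforms measure many genes with several probesets. For each
#' gene the probeset with the largest sample variance of its raw
#' (pre-standardization) values is retained; all other probesets for that
#' gene are discarded. Probesets with no gene mapping are dropped and
#' counted.
#'
#' @param values numeric matrix, probesets x samples, rownames = probeset
#'   IDs.
#' @param probeset_to_gene mapping from probeset to gene: either a named
#'   character vector (names = probeset IDs, values = gene IDs) or a
#'   two-column data frame `(probeset_id, gene_id)`. Many-to-one is allowed.
#' @return A list with elements `values` (gene x sample matrix, rows ordered
#'   by gene ID), `chosen` (data frame `gene_id`, `probeset_id`, `var` for
#'   the retained probeset of each gene) and `n_unmapped` (number of
#'   probesets dropped for lack of a gene mapping).
#' @details Variance uses the sample (n - 1) denominator. Ties in variance
#'   are broken by the lexicographically smallest probeset ID.
#' @export
collapse_probesets <- function(values, probeset_to_gene) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!all(is.finite(values)))
    stop("non-finite values in probeset matrix")
  if (is.data.frame(probeset_to_gene)) {
    map <- stats::setNames(as.character(probeset_to_gene[[2L]]),
                           as.character(probeset_to_gene[[1L]]))
  } else {
    map <- probeset_to_gene
  }
  if (length(map) == 0L)
    stop("no probeset-to-gene mapping")
  if (is.null(names(map)))
    stop("probeset_to_gene must be named by probeset_id")
  bad <- setdiff(names(map), rownames(values))
  if (length(bad) > 0L)
    stop("mapped probeset not in matrix: ", bad[1L])

  mapped <- intersect(rownames(values), names(map))
  n_unmapped <- nrow(values) - length(mapped)
  if (length(mapped) == 0L)
    stop("no probeset-to-gene mapping")

  mu <- rowMeans(values[mapped, , drop = FALSE])
  v <- rowSums((values[mapped, , drop = FALSE] - mu)^2) / (ncol(values) - 1L)
  tab <- data.frame(probeset_id = mapped,
                    gene_id = unname(map[mapped]),
                    var = v, stringsAsFactors = FALSE)
  # max variance per gene; ties -> lexicographically smallest probeset_id
  tab <- tab[order(tab$gene_id, -tab$var, tab$probeset_id), ]
  chosen <- tab[!duplicated(tab$gene_id), ]
  out <- values[chosen$probeset_id, , drop = FALSE]
  rownames(out) <- chosen$gene_id
  list(values = out,
       chosen = data.frame(gene_id = chosen$gene_id,
                           probeset_id = chosen$probeset_id,
                           var = chosen$var, row.names = NULL,
                           stringsAsFactors = FALSE),
       n_unmapped = n_unmapped)
}

#' Standardize a gene-level matrix into an expression compendium
#'
#' Each gene row is transformed to zero mean and unit standard deviation
#' (sample sd, n - 1 denominator). Genes with zero variance are kept as
#' all-zero rows and flagged, so the gene universe stays stable; the
#' correlation stage treats them as invalid. Pre-standardization mean,
#' variance and coefficient of variation are recorded per gene.
#'
#' @param values numeric gene x sample matrix with gene rownames and sample
#'   colnames.
#' @return An [expression_compendium()].
#' @export
standardize_compendium <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (ncol(values) < 2L)
    stop("standardization needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("non-finite values in expression matrix")
  meta <- gene_row_stats(values)
  s <- sqrt(meta$var)
  std <- (values - meta$mean) / ifelse(s == 0, 1, s)
  std[meta$zero_variance, ] <- 0
  expression_compendium(std, meta)
}

meta_path_for <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.tsv")
}

#' Read / write an expression compendium
#'
#' The on-disk format is a tab-delimited UTF-8 matrix (first column
#' `gene_id`, header row of sample IDs, "." decimal) with a sidecar
#' `<name>.meta.tsv` holding the per-gene pre-standardization statistics
#' (`gene_id`, `mean`, `var`, `cv`, `zero_variance`). A `cv` of `Inf` marks
#' genes whose pre-standardization mean is exactly zero.
#'
#' @param path path to the matrix file; the sidecar path is derived from it.
#' @return `read_compendium` returns an [expression_compendium()];
#'   `write_compendium` invisibly returns the two paths written.
#' @export
read_compendium <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L || length(nf) == 1L)
    stop("no data rows in ", path)
  ragged <- which(nf != nf[1L])
  if (length(ragged) > 0L)
    stop("ragged row at line ", ragged[1L], " of ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- ids

  mp <- meta_path_for(path)
  if (!file.exists(mp))
    stop("metadata sidecar not found: ", mp)
  meta <- utils::read.table(mp, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
  meta$gene_id <- as.character(meta$gene_id)
  meta$zero_variance <- as.logical(meta$zero_variance)
  if (!identical(meta$gene_id, ids))
    stop("metadata sidecar does not match matrix gene_ids")
  expression_compendium(m, meta)
}

#' @rdname read_compendium
#' @param cp an `expression_compendium` to write.
#' @export
write_compendium <- function(cp, path) {
  stopifnot(inherits(cp, "expression_compendium"))
  df <- data.frame(gene_id = rownames(cp$values), cp$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  mp <- meta_path_for(path)
  utils::write.table(cp$gene_meta, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(path, mp))
}
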
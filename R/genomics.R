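# Ranked peak list + TSS annotation -> ChIP-only bound-gene ranking.
# Coordinates are 0-based half-open [start, end) internally (BED
# convention); TSS windows are endpoint-inclusive on both sides.

#' Read a ranked peak list from a BED-like file
#'
#' Columns: chrom, start, end, optional name, optional score. When a score
#' column is present, peaks are ranked by descending score (rank 1 =
#' strongest, ties by file order); otherwise file order gives the rank.
#'
#' @param path path to a tab-delimited BED3+/BED5 file (no header).
#' @return A data frame `chrom`, `start`, `end`, `name`, `score`, `rank`,
#'   ordered by rank. Coordinates are 0-based half-open.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no peaks in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", which(nf < 3L)[1L], ": fewer than 3 BED columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- parse_coord(vapply(fields, `[[`, character(1), 2L), "start")
  end <- parse_coord(vapply(fields, `[[`, character(1), 3L), "end")
  bad <- which(start >= end)
  if (length(bad) > 0L)
    stop("line ", bad[1L], ": start >= end")
  name <- vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, character(1))
  has_score <- all(nf >= 5L)
  if (has_score) {
    score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, character(1), 5L)))
    if (anyNA(score))
      stop("line ", which(is.na(score))[1L], ": non-numeric score")
    rank <- integer(length(score))
    rank[order(-score)] <- seq_along(score)
  } else {
    score <- NA_real_
    rank <- seq_along(chrom)
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    score = score, rank = rank, stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}

parse_coord <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0L)
    stop("line ", bad[1L], ": non-integer ", what, " coordinate '",
         x[bad[1L]], "'")
  as.integer(v)
}

#' Read a gene TSS annotation
#'
#' Accepts either a header-led TSV with columns `gene_id`, `chrom`,
#' `strand`, `tss` (0-based TSS position), or a BED6 file of gene bodies
#' (no header), in which case the TSS is `start` for + strand genes and
#' `end - 1` for - strand genes. Multiple records per gene (alternative
#' TSSs) are allowed.
#'
#' @param path path to the annotation file.
#' @return A data frame `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  header_cols <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  if ("gene_id" %in% header_cols) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    if (!all(need %in% names(df)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    df <- df[, need]
    df$gene_id <- as.character(df$gene_id)
    df$chrom <- as.character(df$chrom)
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad) > 0L)
      stop("line ", bad[1L] + 1L, ": unknown strand '", df$strand[bad[1L]],
           "'")
    if (any(df$tss != floor(df$tss)) || anyNA(df$tss))
      stop("non-integer tss coordinate")
    df$tss <- as.integer(df$tss)
    return(df)
  }
  # BED6 gene bodies
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L)
    stop("BED6 annotation needs 6 columns (or use a gene_id TSV header)")
  strand <- as.character(df[[6L]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L)
    stop("line ", bad[1L], ": unknown strand '", strand[bad[1L]], "'")
  start <- df[[2L]]; end <- df[[3L]]
  if (any(start >= end)) stop("line ", which(start >= end)[1L],
                              ": start >= end")
  data.frame(gene_id = as.character(df[[4L]]),
             chrom = as.character(df[[1L]]),
             strand = strand,
             tss = as.integer(ifelse(strand == "+", start, end - 1L)),
             stringsAsFactors = FALSE)
}

# Strand-aware TSS window, endpoint-inclusive, 0-based.
tss_window <- function(tss, strand, upstream, downstream) {
  lo <- ifelse(strand == "+", tss - upstream, tss - downstream)
  hi <- ifelse(strand == "+", tss + downstream, tss + upstream)
  cbind(lo = lo, hi = hi)
}

#' Assign ranked peaks to genes and rank the bound genes
#'
#' A gene is bound when at least one peak falls within its strand-oriented
#' TSS window: `upstream` bases upstream to `downstream` bases downstream of
#' the transcription start site (both boundaries inclusive; for - strand
#' genes upstream means larger coordinates). With `mode = "center"` a peak
#' is "within" the window when its midpoint `floor((start + end)/2)` is;
#' with `mode = "overlap"` one basepair of interval overlap suffices. Each
#' bound gene is scored by its best (smallest) peak rank over all its TSS
#' records, and bound genes are ordered by that rank to give the ChIP-only
#' rank P in `1..G` (ties broken by gene ID).
#'
#' @param peaks data frame as from [read_peaks()] (columns `chrom`, `start`,
#'   `end`, `rank`).
#' @param annotation data frame as from [read_annotation()].
#' @param upstream,downstream window extent in bases (defaults 10000 and
#'   5000).
#' @param mode `"center"` (default) or `"overlap"`.
#' @return An object of class `bound_gene_ranking`: a data frame `gene_id`,
#'   `P`, `best_peak_rank` sorted by `P`.
#' @export
peaks_to_bound_genes <- function(peaks, annotation, upstream = 10000L,
                                 downstream = 5000L,
                                 mode = c("center", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(peaks), is.data.frame(annotation))
  if (nrow(annotation) == 0L) stop("empty annotation")
  if (anyDuplicated(peaks$rank))
    stop("peak ranks must be unique")
  orphan <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
  if (length(orphan) > 0L) {
    warning("peaks on chromosome(s) absent from annotation skipped: ",
            paste(orphan, collapse = ", "))
    peaks <- peaks[!peaks$chrom %in% orphan, , drop = FALSE]
  }

  best <- new.env(parent = emptyenv())
  win <- tss_window(annotation$tss, annotation$strand, upstream, downstream)
  for (chr in unique(annotation$chrom)) {
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (nrow(pk) == 0L) next
    an_i <- which(annotation$chrom == chr)
    # 0-based inclusive [lo, hi] -> 1-based closed IRanges
    subject <- IRanges::IRanges(start = win[an_i, "lo"] + 1L,
                                end = win[an_i, "hi"] + 1L)
    if (mode == "center") {
      mid <- as.integer(floor((pk$start + pk$end) / 2))
      query <- IRanges::IRanges(start = mid + 1L, width = 1L)
    } else {
      query <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    }
    hits <- IRanges::findOverlaps(query, subject)
    if (length(hits) == 0L) next
    g <- annotation$gene_id[an_i[S4Vectors::subjectHits(hits)]]
    r <- pk$rank[S4Vectors::queryHits(hits)]
    agg <- tapply(r, g, min)
    for (gene in names(agg)) {
      prev <- best[[gene]]
      if (is.null(prev) || agg[[gene]] < prev) best[[gene]] <- agg[[gene]]
    }
  }
  genes <- ls(best)
  if (length(genes) == 0L) {
    warning("no peaks fall in any TSS window; empty ranking")
    out <- data.frame(gene_id = character(0), P = integer(0),
                      best_peak_rank = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("bound_gene_ranking", "data.frame")
    return(out)
  }
  bpr <- vapply(genes, function(g) as.integer(best[[g]]), integer(1))
  ord <- order(bpr, genes)
  out <- data.frame(gene_id = genes[ord], P = seq_along(ord),
                    best_peak_rank = bpr[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("bound_gene_ranking", "data.frame")
  out
}

#' @export
print.bound_gene_ranking <- function(x, ...) {
  cat("Bound-gene ranking:", nrow(x), "genes\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}
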
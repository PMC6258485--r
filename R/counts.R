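# Guide count tables: read counting, total-read normalization, and
# library-representation QC.
#
# Screens are sequenced with a custom primer that reads exactly the 19
# variable bases of the guide cassette (the +1 G comes from the constant
# CACCG vector flank and is not sequenced), so reads are matched exactly
# against the designed 19-mers by hash lookup.

new_count_table <- function(guides, counts, meta) {
  stopifnot(is.matrix(counts), nrow(counts) == nrow(guides))
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  rownames(counts) <- guides$guide_id
  structure(list(guides = guides, counts = counts, meta = meta),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("guide count table: %d guides x %d sample(s) [%s]\n",
              nrow(x$counts), ncol(x$counts),
              join_csv(colnames(x$counts))))
  invisible(x)
}

#' Count guide-matching reads from FASTQ
#'
#' The first 19 nt of every read are matched exactly (no mismatch tolerance)
#' against the library's 19-nt spacers; each match increments its guide,
#' anything else is tallied as unassigned. Several FASTQ files give several
#' sample columns.
#'
#' @param fastq Named character vector: sample name -> FASTQ path. An
#'   unnamed single path uses `sample` as its name.
#' @param library `guide_library` object (targeting guides + controls).
#' @param sample Sample name used when `fastq` is unnamed.
#' @return A `count_table`: list with `guides` (guide_id, gene), integer
#'   matrix `counts`, and per-sample `meta` (total, assigned, unassigned).
#' @export
count_reads <- function(fastq, library, sample = "sample") {
  map <- library_spacer_map(library)
  if (nrow(map) == 0) stop("empty guide library", call. = FALSE)
  if (anyDuplicated(map$spacer19))
    stop("library spacers are not unique; counts would be ambiguous",
         call. = FALSE)
  if (is.null(names(fastq))) {
    names(fastq) <- if (length(fastq) == 1) sample else
      paste0(sample, seq_along(fastq))
  }
  counts <- matrix(0L, nrow = nrow(map), ncol = length(fastq),
                   dimnames = list(map$guide_id, names(fastq)))
  meta <- data.frame(sample = names(fastq), total = 0L, assigned = 0L,
                     unassigned = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(fastq)) {
    reads <- read_fastq(fastq[[k]])
    if (any(nchar(reads) < 19))
      stop("read shorter than 19 nt in ", fastq[[k]], call. = FALSE)
    key <- substr(reads, 1L, 19L)
    idx <- match(key, map$spacer19)
    tab <- table(factor(idx[!is.na(idx)], levels = seq_len(nrow(map))))
    counts[, k] <- as.integer(tab)
    meta$total[k] <- length(reads)
    meta$assigned[k] <- sum(!is.na(idx))
    meta$unassigned[k] <- sum(is.na(idx))
  }
  new_count_table(data.frame(guide_id = map$guide_id, gene = map$gene,
                             stringsAsFactors = FALSE),
                  counts, meta)
}

#' Write a count table in the MAGeCK-style layout
#'
#' Columns: sgRNA, gene, then one column per sample.
#' @param table `count_table`.
#' @param path Output path.
#' @export
write_count_table <- function(table, path) {
  out <- data.frame(sgRNA = table$guides$guide_id, gene = table$guides$gene,
                    table$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAGeCK-style count table (sgRNA, gene, sample columns)
#'
#' Accepts the published raw-count layout directly: a "plasmid" column as the
#' pre-screen control and one column per selection.
#'
#' @param path TSV path.
#' @return `count_table`.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_col <- names(tab)[1]
  gene_col <- names(tab)[2]
  samples <- names(tab)[-(1:2)]
  counts <- as.matrix(tab[, samples, drop = FALSE])
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample = samples, total = colSums(counts),
                     assigned = colSums(counts), unassigned = 0L,
                     stringsAsFactors = FALSE)
  new_count_table(data.frame(guide_id = as.character(tab[[id_col]]),
                             gene = as.character(tab[[gene_col]]),
                             stringsAsFactors = FALSE),
                  counts, meta)
}

#' Normalize counts by total reads
#'
#' Scales every sample to a common total (counts per million by default);
#' within-sample ratios are preserved exactly.
#'
#' @param table `count_table` (or the result of a previous normalization).
#' @param scale Common total after normalization (default 1e6).
#' @return An object of class `normalized_counts`: list with `normalized`
#'   (numeric matrix), `size_factors` (per sample: scale / raw total, the
#'   factor each sample is multiplied by), `guides`.
#' @export
normalize_total <- function(table, scale = 1e6) {
  counts <- if (inherits(table, "normalized_counts")) table$normalized
            else table$counts
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[which(totals <= 0)[1]]
    stop("sample ", bad, " has zero total reads", call. = FALSE)
  }
  size_factors <- scale / totals
  normalized <- sweep(counts, 2, size_factors, "*")
  structure(list(normalized = normalized,
                 size_factors = stats::setNames(size_factors,
                                                colnames(counts)),
                 guides = table$guides),
            class = "normalized_counts")
}

#' Library-representation QC for one sample
#'
#' Reports the fraction of guides detected (count > 0), the fraction whose
#' counts fall within `fold_window` of a high-percentile reference count C
#' (i.e. inside [C / fold_window, C]; C defaults to the 99.9th-percentile
#' count), the Gini coefficient of the counts, and a ranked-abundance table
#' for plotting. A well-maintained library keeps most guides within two
#' orders of magnitude.
#'
#' @param table `count_table`.
#' @param sample Sample name.
#' @param fold_window Width of the abundance window (default 100).
#' @param ref_quantile Quantile defining the reference count C (default
#'   0.999).
#' @return list with `fraction_detected`, `fraction_within_window`, `gini`,
#'   `reference_count`, and `ranked` (rank, count).
#' @export
library_complexity_stats <- function(table, sample, fold_window = 100,
                                     ref_quantile = 0.999) {
  if (!sample %in% colnames(table$counts))
    stop("no sample ", sample, " in count table", call. = FALSE)
  x <- table$counts[, sample]
  C <- as.numeric(stats::quantile(x, ref_quantile, type = 1))
  within <- x >= C / fold_window & x <= C
  # Gini over guide counts (0 = perfectly even representation)
  xs <- sort(as.numeric(x))
  n <- length(xs)
  gini <- if (sum(xs) == 0) 0 else
    (2 * sum(seq_len(n) * xs) / (n * sum(xs))) - (n + 1) / n
  list(fraction_detected = mean(x > 0),
       fraction_within_window = mean(within),
       gini = gini,
       reference_count = C,
       ranked = data.frame(rank = seq_len(n), count = sort(x, decreasing = TRUE)))
}
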
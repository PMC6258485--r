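# Readers and writers for the standard formats the tool consumes and emits.
# Genome FASTA and FASTQ go through Biostrings; BED/GTF through rtracklayer.

#' Read a genome FASTA into a named character vector
#'
#' Contig sequences are upper-cased and validated against the ACGTN alphabet.
#' All package functions that take a `genome` argument accept the return value
#' of this function (or any named character vector of ACGTN strings).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA string per contig.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome <- toupper(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(ss))
  validate_genome(genome)
}

#' @keywords internal
validate_genome <- function(genome) {
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome contigs must have unique names", call. = FALSE)
  if (any(!nzchar(genome)))
    stop("genome contains an empty contig", call. = FALSE)
  stopifnot_dna(genome, "genome", "ACGTN")
  genome
}

#' Write a genome to FASTA
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read CAGE peaks from BED
#'
#' BED6, 0-based half-open as usual for the format. The `name` column carries
#' the gene id, `score` the CAGE tag count. If the file has a thickStart
#' column (BED12-style), it is taken as the peak summit; otherwise the summit
#' defaults to the interval midpoint. Coordinates are converted to the
#' package-wide 1-based inclusive convention.
#'
#' @param path BED file path.
#' @return data.frame with columns gene_id, contig, strand, start, end,
#'   summit, tag_count (1-based inclusive start/end).
#' @export
read_cage_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    gene_id = as.character(gr$name),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  df$tag_count <- if (!is.null(gr$score)) as.numeric(gr$score) else 0
  thick <- if ("thick" %in% names(S4Vectors::mcols(gr))) {
    GenomicRanges::start(gr$thick)
  } else {
    NA_integer_
  }
  df$summit <- ifelse(is.na(thick) | thick < df$start | thick > df$end,
                      floor((df$start + df$end) / 2), thick)
  validate_cage_peaks(df)
}

#' @keywords internal
validate_cage_peaks <- function(peaks) {
  req <- c("gene_id", "contig", "strand", "start", "end", "summit", "tag_count")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) stop("cage peaks missing columns: ", join_csv(miss), call. = FALSE)
  if (any(peaks$end < peaks$start))
    stop("cage peak with end < start", call. = FALSE)
  bad <- peaks$summit < peaks$start | peaks$summit > peaks$end
  if (any(bad))
    stop("cage peak summit outside its interval for gene ",
         peaks$gene_id[which(bad)[1]], call. = FALSE)
  peaks
}

#' Read transcript records from GTF or TSV
#'
#' From GTF, `transcript` features are used; the transcription start is the
#' strand-aware 5' end. The annotation tier (\code{cage}, \code{principal} or
#' \code{refseq_nm}) is read from the attribute named by `tier_attribute`
#' (records without it default to \code{refseq_nm}). The TSV dialect has
#' columns gene_id, transcript_id, contig, strand, tss_position, tier.
#'
#' @param path GTF (.gtf) or TSV file.
#' @param tier_attribute GTF attribute key holding the tier label.
#' @return data.frame with columns gene_id, transcript_id, contig, strand,
#'   tss_position, tier.
#' @export
read_transcripts <- function(path, tier_attribute = "tier") {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "GTF")
    gr <- gr[gr$type == "transcript"]
    strand <- as.character(GenomicRanges::strand(gr))
    tss <- ifelse(strand == "-", GenomicRanges::end(gr), GenomicRanges::start(gr))
    tier <- if (tier_attribute %in% names(S4Vectors::mcols(gr))) {
      as.character(S4Vectors::mcols(gr)[[tier_attribute]])
    } else {
      NA_character_
    }
    tier[is.na(tier)] <- "refseq_nm"
    df <- data.frame(
      gene_id = as.character(gr$gene_id),
      transcript_id = as.character(gr$transcript_id),
      contig = as.character(GenomicRanges::seqnames(gr)),
      strand = strand,
      tss_position = tss,
      tier = tier,
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  validate_transcripts(df)
}

#' @keywords internal
validate_transcripts <- function(tx) {
  req <- c("gene_id", "transcript_id", "contig", "strand", "tss_position", "tier")
  miss <- setdiff(req, names(tx))
  if (length(miss)) stop("transcripts missing columns: ", join_csv(miss), call. = FALSE)
  if (!all(tx$tier %in% c("cage", "principal", "refseq_nm")))
    stop("transcript tier must be one of cage/principal/refseq_nm", call. = FALSE)
  if (any(tx$tss_position < 1))
    stop("tss_position must be >= 1", call. = FALSE)
  tx
}

#' Write a FASTQ file
#'
#' Fixed quality "I" for every base; plain text (optionally gzipped by
#' extension).
#'
#' @param reads Character vector of read sequences.
#' @param path Output path (.fastq or .fastq.gz).
#' @param ids Optional read names.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%0*d", nchar(length(reads)) + 1L,
                                   seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file into a character vector of reads
#' @param path FASTQ path (optionally gzipped).
#' @return Character vector of read sequences (uppercase).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  toupper(as.character(ss))
}
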
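# Transcription start site selection and promoter window extraction.
#
# CRISPRa guides act within a narrow window upstream of the TSS, so the whole
# design hinges on picking good start sites. A three-tier hierarchy is used
# per gene: empirically mapped CAGE tag clusters first (the two broadest peaks
# per gene, TSS = peak summit), then transcripts annotated as "principal",
# then any RefSeq NM transcript. Tiers are never mixed within a gene.

#' Select transcription start sites per gene
#'
#' Applies the CAGE > principal > RefSeq-NM hierarchy gene by gene. When a
#' gene has CAGE peaks, the two broadest (widest) peaks are chosen (one if
#' only one exists) and the TSS is the peak summit; width ties are broken by
#' higher tag count, then by the 5'-most peak on the gene strand. Fallback
#' tiers contribute all distinct TSS positions (capped by `max_fallback_tss`
#' if set). Genes with no source in any tier yield no selection and a warning.
#'
#' @param genes Character vector of gene ids to design for.
#' @param cage_peaks data.frame as from [read_cage_peaks()] (or NULL).
#' @param transcripts data.frame as from [read_transcripts()] (or NULL).
#' @param max_cage_peaks Number of CAGE peaks kept per gene (default 2).
#' @param max_fallback_tss Cap on distinct fallback TSS per gene
#'   (default `Inf`, i.e. all distinct positions).
#' @return data.frame with columns gene_id, tss_id, contig, strand,
#'   tss_position, tier, provenance. `tss_id` is unique within each gene.
#' @export
select_tss <- function(genes, cage_peaks = NULL, transcripts = NULL,
                       max_cage_peaks = 2, max_fallback_tss = Inf) {
  if (!is.null(cage_peaks)) {
    validate_cage_peaks(cage_peaks)
    extra <- setdiff(cage_peaks$gene_id, genes)
    if (length(extra))
      stop("cage peak gene ids not in gene list: ", join_csv(extra), call. = FALSE)
  }
  if (!is.null(transcripts)) {
    validate_transcripts(transcripts)
    extra <- setdiff(transcripts$gene_id, genes)
    if (length(extra))
      stop("transcript gene ids not in gene list: ", join_csv(extra), call. = FALSE)
  }

  out <- lapply(genes, function(g) {
    pk <- if (is.null(cage_peaks)) NULL else
      cage_peaks[cage_peaks$gene_id == g, , drop = FALSE]
    if (!is.null(pk) && nrow(pk) > 0) {
      width <- pk$end - pk$start + 1L
      # broadest first; ties: higher tag count, then 5'-most on gene strand
      five_prime <- ifelse(pk$strand == "-", -pk$end, pk$start)
      ord <- order(-width, -pk$tag_count, five_prime)
      pk <- pk[utils::head(ord, max_cage_peaks), , drop = FALSE]
      return(data.frame(
        gene_id = g,
        tss_id = sprintf("%s_cage_%d", g, seq_len(nrow(pk))),
        contig = pk$contig, strand = pk$strand,
        tss_position = pk$summit, tier = "cage",
        provenance = sprintf("cage:%s:%d-%d", pk$contig, pk$start, pk$end),
        stringsAsFactors = FALSE
      ))
    }
    tx <- if (is.null(transcripts)) NULL else
      transcripts[transcripts$gene_id == g, , drop = FALSE]
    for (tier in c("principal", "refseq_nm")) {
      tt <- if (is.null(tx)) NULL else tx[tx$tier == tier, , drop = FALSE]
      if (!is.null(tt) && nrow(tt) > 0) {
        # deduplicate identical (contig, strand, position); keep first record
        key <- paste(tt$contig, tt$strand, tt$tss_position)
        tt <- tt[!duplicated(key), , drop = FALSE]
        tt <- tt[order(tt$contig, tt$tss_position), , drop = FALSE]
        tt <- utils::head(tt, max_fallback_tss)
        return(data.frame(
          gene_id = g,
          tss_id = sprintf("%s_%s_%d", g, tier, seq_len(nrow(tt))),
          contig = tt$contig, strand = tt$strand,
          tss_position = tt$tss_position, tier = tier,
          provenance = paste0("transcript:", tt$transcript_id),
          stringsAsFactors = FALSE
        ))
      }
    }
    warning("gene ", g, " has no TSS source in any tier; skipped",
            call. = FALSE)
    NULL
  })
  sel <- do.call(rbind, out)
  if (is.null(sel)) {
    sel <- data.frame(gene_id = character(0), tss_id = character(0),
                      contig = character(0), strand = character(0),
                      tss_position = integer(0), tier = character(0),
                      provenance = character(0), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(paste(sel$gene_id, sel$tss_id)))
    stop("duplicate tss_id within a gene", call. = FALSE)
  rownames(sel) <- NULL
  sel
}

#' Extract promoter windows around selected TSSs
#'
#' The promoter window spans 450 to 50 bp upstream of the TSS (inclusive
#' coordinate range, so 401 nt by default). On the plus strand and for a
#' 1-based TSS t this is genomic positions [t-up, t-down]; on the minus
#' strand, [t+down, t+up]. Windows running off a contig end are clipped and
#' flagged `truncated`; a window entirely off-contig is an error. The
#' reported sequence is always the plus-strand genomic substring.
#'
#' @param tss data.frame as from [select_tss()].
#' @param genome Named character vector of contig sequences
#'   (see [read_genome()]).
#' @param upstream,downstream Window edges in bp upstream of the TSS
#'   (defaults 450 and 50).
#' @return data.frame with columns gene_id, tss_id, contig, strand,
#'   start, end (1-based inclusive), tss_position, sequence, truncated.
#' @export
promoter_windows <- function(tss, genome, upstream = 450, downstream = 50) {
  validate_genome(genome)
  if (upstream <= downstream)
    stop("upstream must exceed downstream", call. = FALSE)
  missing_contig <- setdiff(tss$contig, names(genome))
  if (length(missing_contig))
    stop("contig(s) not in genome: ", join_csv(missing_contig), call. = FALSE)

  t <- tss$tss_position
  plus <- tss$strand != "-"
  start <- ifelse(plus, t - upstream, t + downstream)
  end <- ifelse(plus, t - downstream, t + upstream)
  clen <- nchar(genome)[tss$contig]
  cstart <- pmax(start, 1L)
  cend <- pmin(end, clen)
  dead <- cstart > cend
  if (any(dead)) {
    i <- which(dead)[1]
    stop(sprintf("promoter window for %s/%s lies entirely off contig %s",
                 tss$gene_id[i], tss$tss_id[i], tss$contig[i]), call. = FALSE)
  }
  out <- data.frame(
    gene_id = tss$gene_id, tss_id = tss$tss_id, contig = tss$contig,
    strand = tss$strand, start = as.integer(cstart), end = as.integer(cend),
    tss_position = t,
    sequence = substr(genome[tss$contig], cstart, cend),
    truncated = (cstart != start) | (cend != end),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
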
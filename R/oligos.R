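# Synthesis oligo formatting and in-silico Golden-Gate (BbsI) cloning checks.
#
# Pooled libraries are synthesized as 77-mer single-stranded oligos: a 39-nt
# 5' flank, the 19-nt variable spacer, and a 19-nt 3' flank. Each flank
# carries one BbsI recognition site oriented inward, so digesting the
# PCR-amplified double-stranded oligo releases a 24-bp insert
# (CACCG + spacer) with 4-nt 5' overhangs (CACC / AAAC) compatible with the
# BbsI-linearized expression vector. Individually cloned guides are ordered
# directly as the annealed 24-mer pair.

#' 5' constant flank of the 77-mer synthesis oligo (39 nt)
#' @export
OLIGO_FLANK5 <- "GCAGATGGCTCTTTGTCCTAGACATCGAAGACAACACCG"

#' 3' constant flank of the 77-mer synthesis oligo (19 nt)
#' @export
OLIGO_FLANK3 <- "GTTTTAGTCTTCTCGTCGC"

# BbsI: recognition GAAGAC, cuts 2 nt (top) / 6 nt (bottom) downstream,
# leaving 4-nt 5' overhangs.
BBSI_TOP_OFFSET <- 2L
BBSI_BOTTOM_OFFSET <- 6L

#' Format a 77-mer synthesis oligo
#'
#' Concatenates the constant flanks around the 19-nt spacer. Errors on wrong
#' spacer length, non-ACGT characters, or an internal BbsI site (which would
#' create a third cut site and destroy the insert during digestion).
#'
#' @param spacer19 Character vector of 19-nt spacers.
#' @return Character vector of 77-nt oligo sequences.
#' @export
format_synthesis_oligo <- function(spacer19) {
  stopifnot_dna(spacer19, "spacer")
  if (any(nchar(spacer19) != 19))
    stop("spacer must be 19 nt", call. = FALSE)
  bad <- has_bbsi_context(spacer19)
  if (any(bad))
    stop("spacer creates an extra BbsI site in the oligo: ",
         spacer19[which(bad)[1]], call. = FALSE)
  paste0(OLIGO_FLANK5, spacer19, OLIGO_FLANK3)
}

#' Digest a 77-mer oligo with BbsI in silico
#'
#' Locates the two inward-facing BbsI sites (GAAGAC on the top strand in the
#' 5' flank, GTCTTC = bottom-strand GAAGAC in the 3' flank), applies the
#' (2/6) cut geometry, and returns the released guide-containing insert as
#' its 24-nt top strand plus the two 4-nt 5' overhangs.
#'
#' @param oligo Character scalar, a 77-mer from [format_synthesis_oligo()]
#'   (any double-cut BbsI substrate is accepted).
#' @return list with `top_strand` (24 nt, CACCG + spacer), `left_overhang`
#'   ("CACC") and `right_overhang` ("AAAC").
#' @export
bbsi_digest <- function(oligo) {
  stopifnot(length(oligo) == 1)
  top_sites <- gregexpr(BBSI_SITES[1], oligo, fixed = TRUE)[[1]]
  bot_sites <- gregexpr(BBSI_SITES[2], oligo, fixed = TRUE)[[1]]
  top_sites <- top_sites[top_sites > 0]
  bot_sites <- bot_sites[bot_sites > 0]
  if (length(top_sites) != 1 || length(bot_sites) != 1)
    stop(sprintf("expected exactly one BbsI site per strand, found %d + %d",
                 length(top_sites), length(bot_sites)), call. = FALSE)

  # top-strand site GAAGAC at position p: top cut after p+5+2, bottom cut
  # after p+5+6 (both counted on top-strand coordinates)
  p <- top_sites
  left_top_cut <- p + 6L + BBSI_TOP_OFFSET - 1L      # last top base of left fragment
  left_bottom_cut <- p + 6L + BBSI_BOTTOM_OFFSET - 1L

  # bottom-strand site (GTCTTC on top) at position q: cuts mirror leftward
  q <- bot_sites
  right_top_cut <- q - BBSI_BOTTOM_OFFSET - 1L       # last top base of insert
  right_bottom_cut <- q - BBSI_TOP_OFFSET - 1L

  insert_top <- substr(oligo, left_top_cut + 1L, right_top_cut)
  left_overhang <- substr(oligo, left_top_cut + 1L, left_bottom_cut)
  right_overhang <- revcomp(substr(oligo, right_top_cut + 1L, right_bottom_cut))
  list(top_strand = insert_top,
       left_overhang = left_overhang,
       right_overhang = right_overhang)
}

#' Format the annealed 24-mer oligo pair for individual cloning
#'
#' Top oligo is CACCG + spacer; bottom oligo is AAAC + reverse complement of
#' the spacer + C. Annealed, they reproduce the duplex released by BbsI
#' digestion of the 77-mer (same top strand and 5' overhangs).
#'
#' @param spacer19 Character vector of 19-nt spacers.
#' @return data.frame with columns top, bottom (both 24 nt).
#' @export
format_annealed_pair <- function(spacer19) {
  stopifnot_dna(spacer19, "spacer")
  if (any(nchar(spacer19) != 19))
    stop("spacer must be 19 nt", call. = FALSE)
  data.frame(top = paste0("CACCG", spacer19),
             bottom = paste0("AAAC", revcomp(spacer19), "C"),
             stringsAsFactors = FALSE)
}

#' Write the synthesis oligo pool
#'
#' @param library `guide_library` object.
#' @param path Output path.
#' @param format "fasta" or "txt" (one sequence per line, vendor style).
#' @export
write_oligo_pool <- function(library, path, format = c("fasta", "txt")) {
  format <- match.arg(format)
  map <- library_spacer_map(library)
  oligos <- format_synthesis_oligo(map$spacer19)
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(oligos)
    names(ss) <- map$guide_id
    Biostrings::writeXStringSet(ss, path)
  } else {
    writeLines(oligos, path)
  }
  invisible(path)
}

# Sanity check on the printed constants: flank lengths must reconstruct the
# 77-mer and each flank must carry exactly one inward BbsI site.
.check_oligo_constants <- function() {
  stopifnot(nchar(OLIGO_FLANK5) == 39, nchar(OLIGO_FLANK3) == 19,
            nchar(OLIGO_FLANK5) + 19L + nchar(OLIGO_FLANK3) == 77L)
}
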
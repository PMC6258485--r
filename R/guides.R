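# Guide enumeration, filtering, ranking, off-target screening and selection.
#
# The designer walks each promoter window, takes every 19-nt sequence lying
# immediately 5' of an NGG PAM on either strand, discards guides with extreme
# GC content (<30% or >75%), polyT runs (>3 consecutive T, a Pol III
# terminator) or BbsI recognition sites (which would break Golden-Gate
# cloning), ranks survivors by proximity to the TSS, removes guides whose
# spacer occurs exactly in another gene's promoter (unless the genes share a
# declared or overlapping promoter group), and selects up to seven guides per
# TSS, relaxing the GC then polyT rules where needed so that every target
# keeps at least two guides. A 5' G is prepended to every selected spacer for
# efficient U6 transcription.

BBSI_SITES <- c("GAAGAC", "GTCTTC")

# BbsI site anywhere in the cloned context (constant G + spacer): spacers
# beginning with AAGAC/TCTTC complete a site against the flank's terminal G
has_bbsi_context <- function(spacer19) {
  ctx <- paste0("G", spacer19)
  grepl(BBSI_SITES[1], ctx, fixed = TRUE) |
    grepl(BBSI_SITES[2], ctx, fixed = TRUE)
}

empty_candidates <- function() {
  data.frame(gene_id = character(0), tss_id = character(0),
             spacer19 = character(0), strand = character(0),
             contig = character(0), start = integer(0), end = integer(0),
             pam = character(0), gc_fraction = numeric(0),
             distance_to_tss = numeric(0), stringsAsFactors = FALSE)
}

#' Enumerate candidate protospacers in a promoter window
#'
#' Scans both strands of the window sequence for 19-nt spacers immediately
#' 5' of an NGG PAM, with spacer and PAM fully inside the window. Minus-strand
#' sites appear as CCN on the plus strand with the 19-nt spacer 3' of the PAM.
#' Spacers containing N are dropped. Spacer and PAM are reported in
#' protospacer-strand orientation; coordinates are plus-strand genomic,
#' 1-based inclusive, covering the 19-nt protospacer.
#'
#' @param window One row of a [promoter_windows()] data.frame.
#' @return data.frame of candidates with columns gene_id, tss_id, spacer19,
#'   strand, contig, start, end, pam, gc_fraction, distance_to_tss.
#' @export
enumerate_protospacers <- function(window) {
  seq <- toupper(window$sequence)
  L <- nchar(seq)
  if (L < 22) {
    warning("window ", window$tss_id, " shorter than 22 nt; no candidates",
            call. = FALSE)
    return(empty_candidates())
  }
  g0 <- window$start  # genomic coordinate of window position 1

  # plus strand: spacer [i, i+18], PAM [i+19, i+21] with pam[2:3] == "GG"
  i <- seq_len(L - 21L)
  pam_plus <- substring(seq, i + 19L, i + 21L)
  hit <- substring(pam_plus, 2L, 3L) == "GG"
  ip <- i[hit]
  plus <- if (length(ip)) data.frame(
    spacer19 = substring(seq, ip, ip + 18L),
    strand = rep("+", length(ip)),
    start = g0 + ip - 1L, end = g0 + ip + 17L,
    pam = pam_plus[hit],
    stringsAsFactors = FALSE
  ) else NULL

  # minus strand: plus-strand CCN at [j, j+2], spacer (plus coords) [j+3, j+21]
  j <- seq_len(L - 21L)
  cc <- substring(seq, j, j + 1L) == "CC"
  jm <- j[cc]
  minus <- if (length(jm)) data.frame(
    spacer19 = revcomp(substring(seq, jm + 3L, jm + 21L)),
    strand = rep("-", length(jm)),
    start = g0 + jm + 2L, end = g0 + jm + 20L,
    pam = revcomp(substring(seq, jm, jm + 2L)),
    stringsAsFactors = FALSE
  ) else NULL

  cand <- rbind(plus, minus)
  if (is.null(cand) || nrow(cand) == 0) return(empty_candidates())
  cand <- cand[!grepl("N", cand$spacer19, fixed = TRUE), , drop = FALSE]
  if (nrow(cand) == 0) return(empty_candidates())
  mid <- (cand$start + cand$end) / 2
  out <- data.frame(
    gene_id = window$gene_id, tss_id = window$tss_id,
    spacer19 = cand$spacer19, strand = cand$strand,
    contig = window$contig, start = cand$start, end = cand$end,
    pam = cand$pam, gc_fraction = gc_fraction(cand$spacer19),
    distance_to_tss = abs(mid - window$tss_position),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Apply GC, polyT and BbsI sequence filters
#'
#' Rejects candidates with GC fraction below `gc_min` or above `gc_max`
#' (waived under the \code{gc_relaxed} relaxation), a run of more than
#' `max_t_run` consecutive T (waived under \code{polyT_relaxed}), or a BbsI
#' recognition site on either strand (GAAGAC/GTCTTC; never waived). The BbsI
#' scan runs on the cloned context "G" + spacer: a spacer starting with
#' AAGAC or TCTTC completes a third recognition site against the constant
#' G that precedes it in the synthesis oligo, which would destroy the
#' insert during Golden-Gate assembly. All applicable reasons are recorded;
#' kept candidates that needed a relaxation carry it in a `relaxations`
#' column.
#'
#' @param candidates data.frame from [enumerate_protospacers()].
#' @param gc_min,gc_max GC-fraction bounds (defaults 0.30 and 0.75).
#' @param max_t_run Longest tolerated T homopolymer (default 3).
#' @param relaxations Character subset of c("gc_relaxed", "polyT_relaxed").
#' @return list with elements `kept` (with `relaxations` column) and
#'   `rejected` (with a `reasons` column of comma-joined filter names).
#' @export
apply_sequence_filters <- function(candidates, gc_min = 0.30, gc_max = 0.75,
                                   max_t_run = 3, relaxations = character(0)) {
  stopifnot(all(relaxations %in% c("gc_relaxed", "polyT_relaxed")))
  n <- nrow(candidates)
  gc_low <- candidates$gc_fraction < gc_min
  gc_high <- candidates$gc_fraction > gc_max
  polyT <- grepl(strrep("T", max_t_run + 1L), candidates$spacer19, fixed = TRUE)
  bbsi <- has_bbsi_context(candidates$spacer19)

  reasons <- mapply(function(a, b, c, d) {
    join_csv(c("gc_low", "gc_high", "polyT", "bbsi")[c(a, b, c, d)])
  }, gc_low, gc_high, polyT, bbsi, USE.NAMES = FALSE)
  if (n == 0) reasons <- character(0)

  gc_fail <- (gc_low | gc_high) & !("gc_relaxed" %in% relaxations)
  polyT_fail <- polyT & !("polyT_relaxed" %in% relaxations)
  reject <- gc_fail | polyT_fail | bbsi

  kept <- candidates[!reject, , drop = FALSE]
  used <- mapply(function(g, p) {
    join_csv(c(
      if (g && "gc_relaxed" %in% relaxations) "gc_relaxed",
      if (p && "polyT_relaxed" %in% relaxations) "polyT_relaxed"
    ))
  }, (gc_low | gc_high)[!reject], polyT[!reject], USE.NAMES = FALSE)
  kept$relaxations <- if (nrow(kept)) used else character(0)

  rejected <- candidates[reject, , drop = FALSE]
  rejected$reasons <- reasons[reject]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Rank candidates of one TSS by proximity to it
#'
#' Distance is measured from the protospacer midpoint to the TSS. Candidates
#' are sorted by ascending distance; ties are broken by plus strand first,
#' then lexicographic spacer sequence. Adds/overwrites a `rank` column.
#'
#' @param candidates Candidates of a single (gene, tss).
#' @param tss_position 1-based TSS coordinate (defaults to the distance
#'   already stored on the candidates).
#' @return The candidates sorted with a `rank` column 1..n.
#' @export
rank_by_tss_proximity <- function(candidates, tss_position = NULL) {
  if (!is.null(tss_position)) {
    mid <- (candidates$start + candidates$end) / 2
    candidates$distance_to_tss <- abs(mid - tss_position)
  }
  ord <- order(candidates$distance_to_tss,
               candidates$strand != "+",
               candidates$spacer19)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Build a 19-mer -> gene-id lookup over all promoter windows, both strands.
window_kmer_index <- function(windows, k = 19L) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(windows))) {
    for (s in c(windows$sequence[i], revcomp(windows$sequence[i]))) {
      L <- nchar(s)
      if (L < k) next
      kmers <- unique(substring(s, 1:(L - k + 1L), k:L))
      for (km in kmers) {
        idx[[km]] <- unique(c(idx[[km]], windows$gene_id[i]))
      }
    }
  }
  idx
}

# Shared-promoter groups: user-declared families plus automatically derived
# groups of genes whose promoter windows overlap genomically (>= 1 bp).
# Returned as a list of character vectors (connected components).
derive_shared_groups <- function(windows, user_groups = list()) {
  genes <- unique(windows$gene_id)
  for (gset in user_groups) {
    unknown <- setdiff(gset, genes)
    if (length(unknown))
      stop("shared group names unknown gene id(s): ", join_csv(unknown),
           call. = FALSE)
  }
  parent <- stats::setNames(genes, genes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[[ra]] <<- rb }

  # genomic overlap between windows of different genes
  n <- nrow(windows)
  if (n > 1) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(windows$start, windows$end),
      IRanges::IRanges(windows$start, windows$end)
    )
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    same_contig <- windows$contig[qh] == windows$contig[sh]
    for (p in which(qh < sh & same_contig)) {
      union_(windows$gene_id[qh[p]], windows$gene_id[sh[p]])
    }
  }
  for (gset in user_groups) {
    if (length(gset) > 1) for (g in gset[-1]) union_(gset[1], g)
  }
  roots <- vapply(genes, find, character(1))
  split(genes, roots)
}

#' Remove guides with exact matches in foreign promoters
#'
#' A candidate is removed iff its spacer occurs exactly (either orientation)
#' within the promoter window of a gene other than its own, unless all genes
#' involved belong to one shared-promoter group. Groups are the union of
#' user-declared families and automatically derived groups of genes whose
#' windows overlap genomically. Retained multi-hit guides record the foreign
#' genes in `offtarget_genes`.
#'
#' @param candidates Candidate data.frame (any number of genes).
#' @param windows All promoter windows of the design ([promoter_windows()]).
#' @param shared_groups List of character vectors of gene ids (families).
#' @return list with elements `kept` (with `offtarget_genes` column) and
#'   `removed`.
#' @export
offtarget_filter <- function(candidates, windows, shared_groups = list()) {
  groups <- derive_shared_groups(windows, shared_groups)
  group_of <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                              unlist(groups))
  idx <- window_kmer_index(windows)

  n <- nrow(candidates)
  keep <- logical(n)
  offt <- character(n)
  for (i in seq_len(n)) {
    hits <- idx[[candidates$spacer19[i]]]
    g <- candidates$gene_id[i]
    foreign <- setdiff(hits, g)
    if (length(foreign) == 0) {
      keep[i] <- TRUE
      offt[i] <- ""
    } else {
      gids <- group_of[c(g, foreign)]
      same_group <- !any(is.na(gids)) && length(unique(gids)) == 1L
      keep[i] <- same_group
      offt[i] <- join_csv(sort(foreign))
    }
  }
  kept <- candidates[keep, , drop = FALSE]
  kept$offtarget_genes <- offt[keep]
  removed <- candidates[!keep, , drop = FALSE]
  removed$offtarget_genes <- offt[!keep]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Select guides for one target TSS under the quota/relaxation rules
#'
#' Takes top-ranked strict candidates up to `quota` (seven, as far as
#' possible); if short, appends GC-relaxed survivors, then polyT-relaxed
#' survivors, in rank order, stopping at the quota. If the final count is
#' below `min_guides`, everything available is emitted together with a
#' warning record. BbsI and off-target failures are never relaxed.
#'
#' @param strict Ranked strict-pool candidates (one gene/tss).
#' @param gc_relaxed Ranked candidates admissible only under GC relaxation.
#' @param polyT_relaxed Ranked candidates admissible only with the polyT rule
#'   relaxed (possibly in addition to GC).
#' @param quota Target number of guides (default 7).
#' @param min_guides Minimum acceptable number (default 2).
#' @return list with `selected` (data.frame, `rank` rewritten 1..n over the
#'   selection) and `warning` (NULL or a message string).
#' @export
select_guides_for_target <- function(strict, gc_relaxed = NULL,
                                     polyT_relaxed = NULL,
                                     quota = 7, min_guides = 2) {
  pools <- Filter(function(p) !is.null(p) && nrow(p) > 0,
                  list(strict, gc_relaxed, polyT_relaxed))
  picked <- list()
  n_have <- 0L
  for (pool in pools) {
    if (n_have >= quota) break
    take <- utils::head(pool[order(pool$rank), , drop = FALSE], quota - n_have)
    picked[[length(picked) + 1L]] <- take
    n_have <- n_have + nrow(take)
  }
  sel <- if (length(picked)) {
    do.call(rbind, picked)
  } else if (length(pools)) {
    pools[[1]][0, , drop = FALSE]
  } else {
    e <- empty_candidates()
    e$relaxations <- character(0)
    e
  }
  warn <- NULL
  if (nrow(sel) < min_guides) {
    tgt <- if (length(pools)) pools[[1]]$tss_id[1] else "<unknown>"
    warn <- sprintf("target %s has only %d guide(s) after full relaxation",
                    tgt, nrow(sel))
  }
  if (nrow(sel)) sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  list(selected = sel, warning = warn)
}

#' Prepend the 5' G used for U6-driven transcription
#'
#' The cloned spacer is always "G" followed by the 19-nt spacer (length 20),
#' even when the spacer already starts with G.
#'
#' @param spacer19 Character vector of 19-nt spacers.
#' @return Character vector of 20-nt cloned spacers.
#' @export
finalize_cloned_spacer <- function(spacer19) {
  stopifnot_dna(spacer19, "spacer")
  if (any(nchar(spacer19) != 19))
    stop("spacers must be 19 nt", call. = FALSE)
  paste0("G", spacer19)
}

#' Select non-targeting control guides
#'
#' Accepts, in pool order, sequences with no match in the genome on either
#' strand within `max_mismatch` substitutions (Hamming distance over every
#' 19-mer genomic window). Pool sequences containing a BbsI site are skipped
#' up front (they could not be cloned into the library). Errors if the pool
#' is exhausted before `n` sequences are accepted.
#'
#' @param pool Character vector of candidate 19-nt sequences.
#' @param genome Named character vector of contig sequences.
#' @param n Number of controls wanted (500 at library scale).
#' @param max_mismatch Maximum tolerated Hamming distance (default 2).
#' @return data.frame with columns control_id, spacer19.
#' @export
select_nontargeting_controls <- function(pool, genome, n = 500,
                                         max_mismatch = 2) {
  validate_genome(genome)
  stopifnot_dna(pool, "control pool")
  if (any(nchar(pool) != 19)) stop("pool sequences must be 19 nt", call. = FALSE)
  pool <- pool[!has_bbsi_context(pool)]
  subjects <- c(
    lapply(genome, Biostrings::DNAString),
    lapply(genome, function(s) Biostrings::reverseComplement(Biostrings::DNAString(s)))
  )
  accepted <- character(0)
  for (s in pool) {
    if (length(accepted) >= n) break
    pat <- Biostrings::DNAString(s)
    hits <- vapply(subjects, function(sub) {
      Biostrings::countPattern(pat, sub, max.mismatch = max_mismatch) > 0L
    }, logical(1))
    if (!any(hits)) accepted <- c(accepted, s)
  }
  if (length(accepted) < n)
    stop(sprintf(
      "control pool exhausted: %d of %d sequences accepted at <=%d mismatches",
      length(accepted), n, max_mismatch), call. = FALSE)
  data.frame(control_id = sprintf("NTC_%04d", seq_len(n)),
             spacer19 = accepted[seq_len(n)], stringsAsFactors = FALSE)
}

#' Generate a random spacer pool for synthetic genomes
#'
#' Seeded generator of candidate 19-mers to feed
#' [select_nontargeting_controls()] when no published pool is supplied.
#'
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @return Character vector of 19-nt sequences.
#' @export
random_spacer_pool <- function(n, seed = NULL) {
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE), collapse = "")
    }, character(1))
  })
}
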
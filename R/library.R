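# Library assembly: orchestrates the per-window design steps into a finished
# guide library and (de)serializes the library table.

#' Design a complete CRISPRa guide library
#'
#' Runs the full design pipeline over a set of promoter windows: protospacer
#' enumeration, sequence filters with tiered relaxation, TSS-proximity
#' ranking, promoter-wide exact off-target removal with shared-group
#' exceptions, per-TSS selection up to the quota, 5' G addition, and
#' (optionally) non-targeting control screening.
#'
#' @param windows Promoter windows from [promoter_windows()].
#' @param genome Named character vector of contig sequences (required when
#'   `n_controls > 0`).
#' @param shared_groups List of character vectors of gene ids declared to
#'   share promoters (gene families).
#' @param quota Guides per TSS (default 7).
#' @param min_guides Minimum guides per TSS before warning (default 2).
#' @param gc_min,gc_max,max_t_run Sequence-filter parameters.
#' @param controls_pool Candidate sequences for non-targeting controls; when
#'   NULL and `n_controls > 0`, a seeded random pool is generated.
#' @param n_controls Number of non-targeting controls (0 to skip).
#' @param max_mismatch Hamming radius for the control genome scan.
#' @param seed Integer seed (controls the random pool only).
#' @return An object of class `guide_library`: list with `guides` (the
#'   library table), `controls`, `per_target` summary, `warnings`, `config`.
#' @export
design_guide_library <- function(windows, genome = NULL,
                                 shared_groups = list(),
                                 quota = 7, min_guides = 2,
                                 gc_min = 0.30, gc_max = 0.75, max_t_run = 3,
                                 controls_pool = NULL, n_controls = 0,
                                 max_mismatch = 2, seed = NULL) {
  config <- list(quota = quota, min_guides = min_guides, gc_min = gc_min,
                 gc_max = gc_max, max_t_run = max_t_run,
                 n_controls = n_controls, max_mismatch = max_mismatch,
                 seed = seed)

  cands <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    enumerate_protospacers(windows[i, , drop = FALSE])
  }))
  if (is.null(cands)) cands <- empty_candidates()

  # Sequence filters at the three relaxation tiers. A candidate enters the
  # most permissive tier it first survives; BbsI failures never survive.
  strict <- apply_sequence_filters(cands, gc_min, gc_max, max_t_run)
  gc_rel <- apply_sequence_filters(cands, gc_min, gc_max, max_t_run,
                                   relaxations = "gc_relaxed")
  full_rel <- apply_sequence_filters(cands, gc_min, gc_max, max_t_run,
                                     relaxations = c("gc_relaxed", "polyT_relaxed"))
  key <- function(d) paste(d$tss_id, d$spacer19, d$strand, d$start)
  tier2 <- gc_rel$kept[!(key(gc_rel$kept) %in% key(strict$kept)), , drop = FALSE]
  tier3 <- full_rel$kept[!(key(full_rel$kept) %in% key(gc_rel$kept)), , drop = FALSE]
  strict_kept <- strict$kept
  strict_kept$relaxations <- rep("", nrow(strict_kept))

  # Off-target screening is never relaxed: apply it to every admissible tier.
  screen <- function(d) {
    if (nrow(d) == 0) { d$offtarget_genes <- character(0); return(d) }
    offtarget_filter(d, windows, shared_groups)$kept
  }
  strict_kept <- screen(strict_kept)
  tier2 <- screen(tier2)
  tier3 <- screen(tier3)

  warnings <- character(0)
  per_target <- list()
  selections <- list()
  targets <- unique(windows[, c("gene_id", "tss_id")])
  for (i in seq_len(nrow(targets))) {
    tid <- targets$tss_id[i]
    pick <- function(d) {
      d <- d[d$tss_id == tid, , drop = FALSE]
      if (nrow(d)) rank_by_tss_proximity(d) else d
    }
    res <- select_guides_for_target(pick(strict_kept), pick(tier2), pick(tier3),
                                    quota = quota, min_guides = min_guides)
    if (!is.null(res$warning)) warnings <- c(warnings, res$warning)
    per_target[[tid]] <- data.frame(
      gene_id = targets$gene_id[i], tss_id = tid,
      n_selected = nrow(res$selected),
      n_relaxed = sum(nzchar(res$selected$relaxations)),
      stringsAsFactors = FALSE
    )
    selections[[tid]] <- res$selected
  }
  guides <- do.call(rbind, selections)
  if (is.null(guides)) {
    guides <- empty_candidates()
    guides$relaxations <- character(0)
    guides$offtarget_genes <- character(0)
    guides$rank <- integer(0)
  }
  # A gene's two windows may overlap; drop byte-identical guide placements.
  dup <- duplicated(paste(guides$gene_id, guides$spacer19, guides$start,
                          guides$strand))
  guides <- guides[!dup, , drop = FALSE]
  rownames(guides) <- NULL

  controls <- NULL
  if (n_controls > 0) {
    if (is.null(genome))
      stop("genome required to screen non-targeting controls", call. = FALSE)
    if (is.null(controls_pool)) {
      controls_pool <- random_spacer_pool(20 * n_controls,
                                          seed = child_seed(seed, "ntc"))
    }
    controls <- select_nontargeting_controls(controls_pool, genome,
                                             n = n_controls,
                                             max_mismatch = max_mismatch)
  }
  build_guide_library(guides, controls, config,
                      per_target = do.call(rbind, per_target),
                      warnings = warnings)
}

#' Assemble a guide library object
#'
#' Validates the selections (spacer length, cloned spacer, BbsI freedom, no
#' cross-gene duplicate spacers) and attaches per-target summaries. Normally
#' called via [design_guide_library()].
#'
#' @param guides Selected targeting guides.
#' @param controls Non-targeting controls (or NULL).
#' @param config Design parameter record.
#' @param per_target Per-TSS summary data.frame.
#' @param warnings Character vector of per-target warnings.
#' @return `guide_library` object.
#' @export
build_guide_library <- function(guides, controls = NULL, config = list(),
                                per_target = NULL, warnings = character(0)) {
  for (col in c("relaxations", "offtarget_genes")) {
    if (is.null(guides[[col]])) guides[[col]] <- rep("", nrow(guides))
  }
  if (is.null(guides$rank)) guides$rank <- seq_len(nrow(guides))
  if (nrow(guides)) {
    if (any(nchar(guides$spacer19) != 19))
      stop("guide with spacer length != 19", call. = FALSE)
    if (any(has_bbsi_context(guides$spacer19)))
      stop("guide with BbsI site survived filtering", call. = FALSE)
    dup <- duplicated(guides$spacer19) | duplicated(guides$spacer19, fromLast = TRUE)
    if (any(dup)) {
      # cross-gene duplicates are legal only when the off-target screen
      # vetted them as a shared-promoter group (offtarget_genes recorded)
      by_spacer <- split(seq_len(nrow(guides))[dup], guides$spacer19[dup])
      for (idx in by_spacer) {
        if (length(unique(guides$gene_id[idx])) > 1 &&
            any(!nzchar(guides$offtarget_genes[idx])))
          stop("spacer duplicated across unrelated genes: ",
               guides$spacer19[idx[1]], call. = FALSE)
      }
    }
    guides$guide_id <- sprintf("%s_g%d", guides$tss_id, guides$rank)
    if (anyDuplicated(guides$guide_id))
      stop("duplicate guide ids", call. = FALSE)
    guides$cloned_spacer <- finalize_cloned_spacer(guides$spacer19)
  } else {
    guides$guide_id <- character(0)
    guides$cloned_spacer <- character(0)
  }
  structure(list(guides = guides, controls = controls, config = config,
                 per_target = per_target, warnings = warnings),
            class = "guide_library")
}

#' @export
print.guide_library <- function(x, ...) {
  cat(sprintf("CRISPRa guide library: %d guides, %d genes, %d controls\n",
              nrow(x$guides), length(unique(x$guides$gene_id)),
              if (is.null(x$controls)) 0L else nrow(x$controls)))
  if (length(x$warnings))
    cat(sprintf("  %d target(s) below the guide quota minimum\n",
                length(x$warnings)))
  invisible(x)
}

#' Write a guide library table
#'
#' TSV with columns guide_id, gene, spacer_19nt, cloned_spacer_20nt, contig,
#' start (1-based), end, strand, tss_id, distance_to_tss, relaxations,
#' offtarget_genes, is_control. Controls carry their id in guide_id, gene
#' "non-targeting" and empty coordinates.
#'
#' @param library `guide_library` object.
#' @param path Output path.
#' @export
write_guide_library <- function(library, path) {
  g <- library$guides
  tab <- data.frame(
    guide_id = g$guide_id, gene = g$gene_id, spacer_19nt = g$spacer19,
    cloned_spacer_20nt = g$cloned_spacer, contig = g$contig,
    start = g$start, end = g$end, strand = g$strand, tss_id = g$tss_id,
    distance_to_tss = g$distance_to_tss, relaxations = g$relaxations,
    offtarget_genes = g$offtarget_genes,
    is_control = rep(FALSE, nrow(g)), stringsAsFactors = FALSE
  )
  if (!is.null(library$controls) && nrow(library$controls)) {
    c0 <- library$controls
    tab <- rbind(tab, data.frame(
      guide_id = c0$control_id, gene = "non-targeting",
      spacer_19nt = c0$spacer19,
      cloned_spacer_20nt = finalize_cloned_spacer(c0$spacer19),
      contig = "", start = NA_integer_, end = NA_integer_, strand = "",
      tss_id = "", distance_to_tss = NA_real_, relaxations = "",
      offtarget_genes = "", is_control = TRUE, stringsAsFactors = FALSE
    ))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide library table written by [write_guide_library()]
#' @param path Library TSV path.
#' @return `guide_library` object (config not recoverable from the table).
#' @export
read_guide_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA", colClasses = c(
                             guide_id = "character", gene = "character",
                             spacer_19nt = "character",
                             cloned_spacer_20nt = "character",
                             contig = "character", strand = "character",
                             tss_id = "character", relaxations = "character",
                             offtarget_genes = "character"))
  for (col in c("relaxations", "offtarget_genes", "contig", "strand", "tss_id"))
    tab[[col]][is.na(tab[[col]])] <- ""
  tg <- tab[!tab$is_control, , drop = FALSE]
  guides <- data.frame(
    gene_id = tg$gene, tss_id = tg$tss_id, spacer19 = tg$spacer_19nt,
    strand = tg$strand, contig = tg$contig, start = tg$start, end = tg$end,
    pam = rep(NA_character_, nrow(tg)),
    gc_fraction = gc_fraction(tg$spacer_19nt),
    distance_to_tss = tg$distance_to_tss,
    relaxations = tg$relaxations, offtarget_genes = tg$offtarget_genes,
    rank = as.integer(sub("^.*_g", "", tg$guide_id)),
    guide_id = tg$guide_id, cloned_spacer = tg$cloned_spacer_20nt,
    stringsAsFactors = FALSE
  )
  ctrl <- tab[tab$is_control, , drop = FALSE]
  controls <- if (nrow(ctrl)) {
    data.frame(control_id = ctrl$guide_id, spacer19 = ctrl$spacer_19nt,
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(guides = guides, controls = controls, config = list(),
                 per_target = NULL, warnings = character(0)),
            class = "guide_library")
}

# All spacers in the library (targeting + controls) with their group labels.
library_spacer_map <- function(library) {
  g <- library$guides
  out <- data.frame(guide_id = g$guide_id, gene = g$gene_id,
                    spacer19 = g$spacer19, stringsAsFactors = FALSE)
  if (!is.null(library$controls) && nrow(library$controls)) {
    out <- rbind(out, data.frame(guide_id = library$controls$control_id,
                                 gene = "non-targeting",
                                 spacer19 = library$controls$spacer19,
                                 stringsAsFactors = FALSE))
  }
  out
}
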
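# Generative simulator of sort-gate CRISPRa enrichment screens, plus a
# synthetic-reference builder with planted guide sites for testing the
# designer by construction.
#
# The screen model: guide abundances in the plasmid pool are log-normal;
# each cell receives a single guide (low-MOI design); a fixed, seeded subset
# of guides is functional (Bernoulli per guide); cells whose functional guide
# targets a true hit gene add a log-normal surface-expression signal on top
# of log-normal staining background; the brightest `sort_fraction` of cells
# are collected; sequencing of plasmid, presort and sorted pools draws
# Dirichlet-multinomial counts (PCR jackpotting) at a fixed read depth.

#' Simulation configuration
#'
#' Defaults are the "desk" profile used throughout the test-suite: 1000
#' genes x 5 guides, 5 hit genes, 2e5 cells, 2e6 reads per sample. The
#' sort gate (5%) and MOI (0.3) follow the published screen design;
#' `plasmid_lognorm_sigma` is set so that roughly 89% of plasmid guide
#' counts fall within a 100-fold abundance window
#' (sigma = log(100) / (z[0.999] - z[0.11]) ~ 1.07, matching the reference
#' count definition in [library_complexity_stats()]).
#'
#' @param n_genes Number of genes in the library.
#' @param guides_per_gene Guides per gene.
#' @param hit_genes Character vector of true hit genes (default none).
#' @param p_guide_active Probability that a guide is functional. Default
#'   0.9: most guides in a well-designed library activate their target, a
#'   minority are inert.
#' @param activation_lognorm c(meanlog, sdlog) of the added surface signal in
#'   cells carrying a functional hit-gene guide.
#' @param background_lognorm c(meanlog, sdlog) of staining background.
#' @param plasmid_lognorm_sigma sdlog of plasmid guide representation.
#' @param n_cells Transduced (BFP-sorted) cells entering selection.
#' @param moi Mean lentiviral integrations per cell (reported in the truth
#'   manifest; cells are modeled single-guide per the low-MOI design).
#' @param sort_fraction Fraction of cells collected at the sort gate.
#' @param reads_per_sample Sequencing depth per sample.
#' @param overdispersion Dirichlet concentration per guide (alpha_i =
#'   overdispersion * n_guides * p_i); larger = closer to multinomial.
#' @param seed Integer seed.
#' @return `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000, guides_per_gene = 5,
                       hit_genes = character(0), p_guide_active = 0.9,
                       activation_lognorm = c(meanlog = 3, sdlog = 1),
                       background_lognorm = c(meanlog = 0, sdlog = 1),
                       plasmid_lognorm_sigma = 1.07,
                       n_cells = 2e5, moi = 0.3, sort_fraction = 0.05,
                       reads_per_sample = 2e6, overdispersion = 1000,
                       seed = 1L) {
  stopifnot(sort_fraction > 0, sort_fraction < 1, moi > 0, n_genes >= 1,
            n_cells >= 1, reads_per_sample >= 1,
            p_guide_active >= 0, p_guide_active <= 1)
  structure(list(
    n_genes = n_genes, guides_per_gene = guides_per_gene,
    hit_genes = hit_genes, p_guide_active = p_guide_active,
    activation_lognorm = activation_lognorm,
    background_lognorm = background_lognorm,
    plasmid_lognorm_sigma = plasmid_lognorm_sigma,
    n_cells = n_cells, moi = moi, sort_fraction = sort_fraction,
    reads_per_sample = reads_per_sample, overdispersion = overdispersion,
    seed = seed
  ), class = "sim_config")
}

#' Screen-mimetic default configurations
#'
#' The "paper" profile mirrors the published screen scale (6213 genes at ~7
#' guides each plus controls, 1e8 stained cells, 5% sort gate, MOI 0.3,
#' ~200x coverage); the "desk" profile (the package default) scales the same
#' generative law down to laptop size.
#'
#' @param profile "desk" (default) or "paper".
#' @param ... Overrides passed to [sim_config()].
#' @return `sim_config` list.
#' @export
default_paper_config <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  base <- if (profile == "paper") {
    list(n_genes = 6213, guides_per_gene = 7, n_cells = 1e8,
         reads_per_sample = 3e7)
  } else {
    list()
  }
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# --- synthetic reference with planted guide sites -------------------------

# Random DNA free of GG/CC dinucleotides (hence free of SpCas9 PAMs on both
# strands), so the only enumerable protospacers in a window are planted ones.
pam_free_sequence <- function(n) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    allowed <- if (prev %in% c("G", "C")) setdiff(bases, prev) else bases
    out[i] <- sample(allowed, 1)
    prev <- out[i]
  }
  paste(out, collapse = "")
}

# One planted 19-nt spacer of a given kind, GG/CC-free so that no accidental
# PAM arises inside it.
planted_spacer <- function(kind = c("valid", "gc_low", "polyT", "bbsi")) {
  kind <- match.arg(kind)
  repeat {
    s <- pam_free_sequence(19)
    gc <- gc_fraction(s)
    has_polyT <- grepl("TTTT", s, fixed = TRUE)
    ok <- switch(kind,
      valid = gc >= 0.35 && gc <= 0.70 && !has_polyT && !has_bbsi_context(s),
      gc_low = gc < 0.25 && !has_polyT && !has_bbsi_context(s),
      polyT = FALSE,  # constructed below
      bbsi = FALSE)
    if (kind == "polyT") {
      # mid-GC spacer with an embedded TTTT run
      s <- paste0(substr(s, 1, 7), "TTTT", substr(s, 12, 19))
      gc <- gc_fraction(s)
      ok <- gc >= 0.30 && gc <= 0.75 &&
        !grepl("GG", s, fixed = TRUE) && !grepl("CC", s, fixed = TRUE) &&
        !has_bbsi_context(s)
    }
    if (kind == "bbsi") {
      s <- paste0(substr(s, 1, 6), "GAAGAC", substr(s, 13, 19))
      ok <- gc_fraction(s) >= 0.30 && gc_fraction(s) <= 0.75 &&
        !grepl("GG", s, fixed = TRUE) && !grepl("CC", s, fixed = TRUE) &&
        !grepl("TTTT", s, fixed = TRUE)
    }
    if (ok) return(s)
  }
}

#' Build a synthetic reference with planted guide sites
#'
#' One contig per gene; each carries a plus-strand TSS whose promoter window
#' contains planted protospacers of known kinds: `n_valid` guides passing
#' every designer rule, plus one GC-failing, one polyT-failing and one
#' BbsI-failing site. Outside the planted sites the sequence contains no
#' GG/CC dinucleotide, so the planted sites are the only enumerable
#' protospacers. Optional `duplicate_pairs` of genes share one extra
#' byte-identical valid spacer (a shared-promoter situation for the
#' off-target filter). CAGE peaks (summit = TSS) and principal transcripts
#' are emitted for the TSS-selection hierarchy.
#'
#' @param n_genes Number of genes.
#' @param n_valid Valid guides planted per gene (default 3).
#' @param duplicate_pairs List of 2-element gene-index vectors sharing a
#'   spacer.
#' @param seed Integer seed.
#' @return list with `genome`, `transcripts`, `cage_peaks`, `genes`,
#'   `family_groups` (the duplicate pairs as gene-id sets), and `truth`
#'   (data.frame: gene_id, spacer19, kind, start, end, strand).
#' @export
make_synthetic_reference <- function(n_genes = 6, n_valid = 3,
                                     duplicate_pairs = list(), seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    contig_len <- 1000L
    tss <- 851L           # plus strand: window [401, 801]
    win_lo <- tss - 450L
    win_hi <- tss - 50L

    shared <- list()
    for (p in seq_along(duplicate_pairs)) {
      pair <- duplicate_pairs[[p]]
      stopifnot(length(pair) == 2)
      shared[[p]] <- list(genes = genes[pair], spacer = planted_spacer("valid"))
    }

    genome <- character(n_genes)
    names(genome) <- genes
    truth <- list()
    for (gi in seq_len(n_genes)) {
      seqchars <- strsplit(pam_free_sequence(contig_len), "")[[1]]
      kinds <- c(rep("valid", n_valid), "gc_low", "polyT", "bbsi")
      extra <- Filter(function(s) gi %in% match(s$genes, genes), shared)
      spacers <- vapply(kinds, planted_spacer, character(1))
      for (s in extra) {
        spacers <- c(spacers, s$spacer)
        kinds <- c(kinds, "valid_shared")
      }
      n_sites <- length(spacers)
      # evenly spaced sites; each occupies spacer(19) + PAM(3) + A spacers
      slot <- floor((win_hi - win_lo - 2L) / n_sites)
      stopifnot(slot >= 24)
      rows <- list()
      for (k in seq_len(n_sites)) {
        pos <- win_lo + 1L + (k - 1L) * slot  # spacer start (genomic, 1-based)
        frag <- strsplit(paste0("A", spacers[k], "TGG", "A"), "")[[1]]
        seqchars[(pos - 1L):(pos + 22L)] <- frag
        rows[[k]] <- data.frame(
          gene_id = genes[gi], spacer19 = spacers[k],
          kind = sub("_shared", "", kinds[k]), shared = grepl("shared", kinds[k]),
          start = pos, end = pos + 18L, strand = "+",
          stringsAsFactors = FALSE)
      }
      genome[gi] <- paste(seqchars, collapse = "")
      truth[[gi]] <- do.call(rbind, rows)
    }
    truth <- do.call(rbind, truth)

    transcripts <- data.frame(
      gene_id = genes, transcript_id = paste0(genes, "_t1"),
      contig = genes, strand = "+", tss_position = tss, tier = "principal",
      stringsAsFactors = FALSE)
    cage_peaks <- data.frame(
      gene_id = genes, contig = genes, strand = "+",
      start = tss - 25L, end = tss + 25L, summit = tss,
      tag_count = stats::rpois(n_genes, 50),
      stringsAsFactors = FALSE)
    family_groups <- lapply(shared, function(s) s$genes)

    list(genome = validate_genome(genome), transcripts = transcripts,
         cage_peaks = cage_peaks, genes = genes,
         family_groups = family_groups, truth = truth)
  })
}

#' Write a synthetic reference bundle to disk
#'
#' FASTA genome, transcript TSV, CAGE-peak BED (1-based internal coordinates
#' converted to BED's 0-based half-open) and a JSON of family groups.
#'
#' @param ref Output of [make_synthetic_reference()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    transcripts = file.path(dir, "transcripts.tsv"),
    cage = file.path(dir, "cage_peaks.bed"),
    groups = file.path(dir, "family_groups.json")
  )
  write_genome(ref$genome, paths[["genome"]])
  utils::write.table(ref$transcripts, paths[["transcripts"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = ref$cage_peaks$contig,
                    start = ref$cage_peaks$start - 1L,
                    end = ref$cage_peaks$end,
                    name = ref$cage_peaks$gene_id,
                    score = ref$cage_peaks$tag_count,
                    strand = ref$cage_peaks$strand)
  utils::write.table(bed, paths[["cage"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(ref$family_groups, paths[["groups"]])
  invisible(paths)
}

#' Generate a synthetic guide library for screen simulation
#'
#' A desk-scale `guide_library` with random unique BbsI-free spacers:
#' `n_genes` x `guides_per_gene` targeting guides plus `n_controls`
#' non-targeting controls. Used to drive [simulate_screen()] when the
#' genomic design path is not under study.
#'
#' @param n_genes,guides_per_gene,n_controls Library dimensions.
#' @param seed Integer seed.
#' @return `guide_library` object.
#' @export
sim_guide_library <- function(n_genes = 1000, guides_per_gene = 5,
                              n_controls = 25, seed = 1L) {
  n <- n_genes * guides_per_gene + n_controls
  spacers <- with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      block <- vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE), collapse = "")
      }, character(1))
      out <- unique(c(out, block[!has_bbsi_context(block)]))
    }
    out[seq_len(n)]
  })
  genes <- rep(sprintf("G%04d", seq_len(n_genes)), each = guides_per_gene)
  nt <- n_genes * guides_per_gene
  guides <- data.frame(
    gene_id = genes, tss_id = paste0(genes, "_t1"),
    spacer19 = spacers[seq_len(nt)], strand = "+",
    contig = "synthetic", start = NA_integer_, end = NA_integer_,
    pam = NA_character_, gc_fraction = gc_fraction(spacers[seq_len(nt)]),
    distance_to_tss = NA_real_, relaxations = "", offtarget_genes = "",
    rank = rep(seq_len(guides_per_gene), n_genes),
    stringsAsFactors = FALSE)
  guides$guide_id <- sprintf("%s_g%d", guides$tss_id, guides$rank)
  guides$cloned_spacer <- finalize_cloned_spacer(guides$spacer19)
  controls <- if (n_controls > 0) {
    data.frame(control_id = sprintf("NTC_%04d", seq_len(n_controls)),
               spacer19 = spacers[nt + seq_len(n_controls)],
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(guides = guides, controls = controls,
                 config = list(synthetic = TRUE, seed = seed),
                 per_target = NULL, warnings = character(0)),
            class = "guide_library")
}

# --- screen simulation ----------------------------------------------------

# Dirichlet-multinomial counts at depth `reads`, concentration per guide
# `conc` (alpha_i = conc * length(p) * p_i).
dirmult_counts <- function(p, reads, conc) {
  alpha <- conc * length(p) * p
  w <- stats::rgamma(length(p), shape = alpha, rate = 1)
  w[alpha == 0] <- 0
  if (sum(w) == 0) stop("degenerate abundance vector", call. = FALSE)
  as.integer(stats::rmultinom(1, reads, w / sum(w)))
}

#' Simulate a sort-gate enrichment screen
#'
#' Draws plasmid abundances, assigns one guide per cell, marks a seeded
#' subset of guides functional, gives cells of functional hit-gene guides an
#' added log-normal surface signal, collects the brightest `sort_fraction`
#' of cells, and sequences plasmid, presort and sorted pools with
#' Dirichlet-multinomial noise. Column sums equal `reads_per_sample`
#' exactly.
#'
#' @param library `guide_library` (targeting guides + controls).
#' @param config `sim_config`; `config$hit_genes` must be library genes.
#' @return list with `counts` (a `count_table` with samples plasmid,
#'   presort, sorted) and `truth` (per-guide manifest: guide_id, gene,
#'   active, is_hit, expected_direction, cells, sorted_cells; attributes
#'   hit_genes, config).
#' @export
simulate_screen <- function(library, config = sim_config()) {
  map <- library_spacer_map(library)
  n_g <- nrow(map)
  if (n_g == 0) stop("empty guide library", call. = FALSE)
  unknown <- setdiff(config$hit_genes, map$gene)
  if (length(unknown))
    stop("hit gene(s) not in library: ", join_csv(unknown), call. = FALSE)
  n_sorted <- floor(config$n_cells * config$sort_fraction)
  if (n_sorted < 1) stop("sorted pool smaller than 1 cell", call. = FALSE)

  with_seed(config$seed, {
    plasmid_w <- stats::rlnorm(n_g, 0, config$plasmid_lognorm_sigma)
    plasmid_p <- plasmid_w / sum(plasmid_w)

    cells <- as.integer(stats::rmultinom(1, config$n_cells, plasmid_p))
    active <- stats::rbinom(n_g, 1, config$p_guide_active) == 1
    is_hit <- map$gene %in% config$hit_genes

    # per-cell staining signal; only (active guide) x (hit gene) cells get
    # the activation component
    guide_of_cell <- rep.int(seq_len(n_g), cells)
    n_cells_real <- length(guide_of_cell)
    signal <- stats::rlnorm(n_cells_real,
                            config$background_lognorm[[1]],
                            config$background_lognorm[[2]])
    boosted <- active[guide_of_cell] & is_hit[guide_of_cell]
    if (any(boosted)) {
      signal[boosted] <- signal[boosted] +
        stats::rlnorm(sum(boosted),
                      config$activation_lognorm[[1]],
                      config$activation_lognorm[[2]])
    }
    top <- guide_of_cell[order(signal, decreasing = TRUE)[seq_len(n_sorted)]]
    sorted_cells <- tabulate(top, nbins = n_g)

    counts <- cbind(
      plasmid = dirmult_counts(plasmid_p, config$reads_per_sample,
                               config$overdispersion),
      presort = dirmult_counts(cells / sum(cells), config$reads_per_sample,
                               config$overdispersion),
      sorted = dirmult_counts(sorted_cells / sum(sorted_cells),
                              config$reads_per_sample, config$overdispersion)
    )
    meta <- data.frame(sample = colnames(counts),
                       total = colSums(counts), assigned = colSums(counts),
                       unassigned = 0L, stringsAsFactors = FALSE)
    tab <- new_count_table(
      data.frame(guide_id = map$guide_id, gene = map$gene,
                 stringsAsFactors = FALSE),
      counts, meta)

    truth <- data.frame(
      guide_id = map$guide_id, gene = map$gene, active = active,
      is_hit = is_hit,
      expected_direction = ifelse(active & is_hit, "up", "none"),
      cells = cells, sorted_cells = sorted_cells,
      stringsAsFactors = FALSE)
    attr(truth, "hit_genes") <- config$hit_genes
    attr(truth, "expected_multiplicity") <- config$moi /
      (1 - exp(-config$moi))  # mean integrations among transduced cells
    list(counts = tab, truth = truth, config = config)
  })
}

#' Emit simulated FASTQ reads for a screen
#'
#' Each guide's 19-nt spacer is written `count` times per sample, with
#' per-base substitution errors at `error_rate`, in shuffled order.
#'
#' @param screen Output of [simulate_screen()] (or any `count_table` via
#'   `screen$counts`).
#' @param library `guide_library` supplying the spacer sequences.
#' @param dir Output directory.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @return Named vector of FASTQ paths (one per sample).
#' @export
simulate_reads <- function(screen, library, dir, error_rate = 0, seed = 1L) {
  counts <- if (inherits(screen, "count_table")) screen else screen$counts
  map <- library_spacer_map(library)
  stopifnot(identical(map$guide_id, counts$guides$guide_id))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  paths <- character(0)
  with_seed(seed, {
    for (s in colnames(counts$counts)) {
      reads <- rep.int(map$spacer19, counts$counts[, s])
      if (error_rate > 0 && length(reads)) {
        m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                    ncol = 19, byrow = TRUE)
        hit <- matrix(stats::runif(length(m)) < error_rate, nrow = nrow(m))
        if (any(hit)) {
          cur <- m[hit]
          m[hit] <- vapply(cur, function(b) sample(setdiff(bases, b), 1),
                           character(1))
        }
        reads <- apply(m, 1, paste, collapse = "")
      }
      if (length(reads)) reads <- sample(reads)
      path <- file.path(dir, paste0(s, ".fastq"))
      write_fastq(reads, path)
      paths[s] <- path
    }
  })
  invisible(paths)
}
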
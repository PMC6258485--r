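# Shared fixture builders. Everything is generated in code; no data files.

# random DNA string (unconstrained alphabet)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# random 19-nt spacer free of BbsI sites in its cloned context (G + spacer)
rand_spacer <- function() {
  repeat {
    s <- rand_dna(19)
    if (!grepl("GAAGAC|GTCTTC", paste0("G", s))) return(s)
  }
}

# a window row as produced by promoter_windows()
fake_window <- function(sequence, gene_id = "G1", tss_id = "G1_t1",
                        start = 1001L, tss_position = NULL, strand = "+") {
  if (is.null(tss_position)) tss_position <- start + nchar(sequence) + 49L
  data.frame(gene_id = gene_id, tss_id = tss_id, contig = "chr1",
             strand = strand, start = start,
             end = start + nchar(sequence) - 1L,
             tss_position = tss_position, sequence = sequence,
             truncated = FALSE, stringsAsFactors = FALSE)
}

# independent quadratic-scan oracle: all (spacer, strand) protospacers with a
# fully contained NGG PAM, both strands, N-containing spacers dropped
naive_protospacer_scan <- function(seq) {
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  for (i in seq_len(max(L - 21L, 0L))) {
    pam <- substr(seq, i + 19L, i + 21L)
    if (substr(pam, 2, 3) == "GG") {
      sp <- substr(seq, i, i + 18L)
      if (!grepl("N", sp, fixed = TRUE))
        out[[length(out) + 1L]] <- c(sp, "+")
    }
  }
  rc <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x),
                                       "")[[1]]), collapse = "")
  for (j in seq_len(max(L - 21L, 0L))) {
    if (substr(seq, j, j + 1L) == "CC") {
      sp <- rc(substr(seq, j + 3L, j + 21L))
      if (!grepl("N", sp, fixed = TRUE))
        out[[length(out) + 1L]] <- c(sp, "-")
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(x) paste(x[1], x[2]), character(1)))
}

# exhaustive alpha-RRA oracle for one gene holding k of n joint ranks:
# enumerate every C(n, k) assignment of rank positions, apply the same
# selection rule (percentile <= n_sel/n) and beta order-statistic score
exhaustive_rra <- function(p_all, gene_idx, alpha) {
  n <- length(p_all)
  perc <- rank(p_all, ties.method = "first") / n
  thresh <- sum(p_all < alpha) / n
  rho_of <- function(r) {
    r <- sort(r)
    k <- length(r)
    sel <- r <= thresh
    if (!any(sel)) return(1)
    j <- which(sel)
    min(stats::pbeta(r[j], j, k - j + 1))
  }
  obs <- rho_of(perc[gene_idx])
  k <- length(gene_idx)
  combos <- utils::combn(n, k)
  null <- apply(combos, 2, function(idx) rho_of(perc[idx]))
  list(obs = obs, p_exact = mean(null <= obs), null = null)
}

# brute-force minimum Hamming distance between a spacer and all 19-mer
# windows of a genome, both strands
naive_min_hamming <- function(spacer, genome) {
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x),
                                       "")[[1]]), collapse = "")
  sv <- strsplit(spacer, "")[[1]]
  best <- Inf
  for (contig in genome) {
    for (s in c(contig, rc(contig))) {
      L <- nchar(s)
      if (L < 19) next
      for (i in 1:(L - 18)) {
        w <- strsplit(substr(s, i, i + 18), "")[[1]]
        best <- min(best, sum(w != sv))
      }
    }
  }
  best
}
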
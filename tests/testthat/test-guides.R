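# Guide enumeration, filtering, ranking, off-target removal, selection,
# controls

test_that("protospacer enumeration matches worked examples", {
  # no GG/CC anywhere: nothing to find
  w <- fake_window(strrep("A", 25))
  expect_equal(nrow(enumerate_protospacers(w)), 0)

  # 19 A's + TGG: exactly one plus-strand candidate
  w <- fake_window(paste0(strrep("A", 19), "TGG"))
  cand <- enumerate_protospacers(w)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$spacer19, strrep("A", 19))
  expect_equal(cand$pam, "TGG")
  expect_equal(cand$strand, "+")
  expect_equal(cand$end - cand$start + 1L, 19L)

  # poly-G window: 9 plus-strand placements, none on the minus strand
  w <- fake_window(strrep("G", 30))
  cand <- enumerate_protospacers(w)
  expect_equal(sum(cand$strand == "+"), 9)
  expect_equal(sum(cand$strand == "-"), 0)

  # too-short window warns and returns nothing
  expect_warning(out <- enumerate_protospacers(fake_window("ACGTACGT")),
                 "shorter than 22")
  expect_equal(nrow(out), 0)
})

test_that("enumeration agrees with a naive quadratic scan on random windows", {
  set.seed(101)
  for (i in 1:40) {
    len <- sample(22:500, 1)
    seq <- rand_dna(len)
    if (i %% 5 == 0) substr(seq, len %/% 2, len %/% 2) <- "N"
    cand <- enumerate_protospacers(fake_window(seq))
    got <- sort(paste(cand$spacer19, cand$strand))
    expect_identical(got, naive_protospacer_scan(seq))
    # coordinates reconstruct the spacer from the window sequence
    if (nrow(cand)) {
      off <- cand$start - 1001L + 1L
      plus_sub <- substring(seq, off, off + 18L)
      rc <- function(x) vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
                               function(s) paste(rev(s), collapse = ""), "")
      expect_identical(ifelse(cand$strand == "+", plus_sub, rc(plus_sub)),
                       cand$spacer19)
    }
  }
})

`%+%` <- function(a, b) paste0(a, b)

test_that("sequence filters flag GC, polyT and BbsI with correct relaxation", {
  mk <- function(s) {
    data.frame(gene_id = "G1", tss_id = "t", spacer19 = s, strand = "+",
               contig = "c", start = 1L, end = 19L, pam = "TGG",
               gc_fraction = crisprascreen:::gc_fraction(s),
               distance_to_tss = 0, stringsAsFactors = FALSE)
  }
  # all-A: gc_low only (no T run at all)
  res <- apply_sequence_filters(mk(strrep("A", 19)))
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$rejected$reasons, "gc_low")

  # BbsI site rejected even under full relaxation
  bb <- paste0("GAAGAC", strrep("ACG", 4), "A")
  res <- apply_sequence_filters(mk(bb),
                                relaxations = c("gc_relaxed", "polyT_relaxed"))
  expect_equal(nrow(res$kept), 0)
  expect_match(res$rejected$reasons, "bbsi")
  res2 <- apply_sequence_filters(mk(paste0("GTCTTC", strrep("ACG", 4), "A")))
  expect_match(res2$rejected$reasons, "bbsi")

  # clean spacer kept; GC computed exactly on the 19-mer
  ok <- "ACGTACGTACGTACGTACG"
  res <- apply_sequence_filters(mk(ok))
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$gc_fraction, 10 / 19)

  # polyT: a run of 4 T rejected strictly, kept under relaxation with flag
  pt <- paste0("ACGTTTTACGACGACGACG")
  expect_equal(nrow(apply_sequence_filters(mk(pt))$kept), 0)
  rel <- apply_sequence_filters(mk(pt), relaxations = "polyT_relaxed")
  expect_equal(rel$kept$relaxations, "polyT_relaxed")

  # high GC rejected, kept under gc_relaxed
  hi <- strrep("GCG", 6) %+% "C"
  expect_equal(apply_sequence_filters(mk(hi))$rejected$reasons, "gc_high")
  expect_equal(nrow(apply_sequence_filters(mk(hi),
                                           relaxations = "gc_relaxed")$kept), 1)
})

test_that("TSS-proximity ranking: distance, stable order, tie-breaks", {
  cand <- data.frame(
    gene_id = "G1", tss_id = "t",
    spacer19 = c("C" %+% strrep("A", 18), "B" %+% strrep("A", 18)),
    strand = c("+", "+"), contig = "c",
    start = c(800L, 700L), end = c(819L, 719L), pam = "TGG",
    gc_fraction = 0.5, distance_to_tss = NA_real_,
    stringsAsFactors = FALSE)
  r <- rank_by_tss_proximity(cand, tss_position = 1000L)
  expect_equal(r$distance_to_tss, c(190.5, 290.5))
  expect_equal(r$rank, 1:2)
  expect_equal(r$start, c(800L, 700L))

  # single candidate -> rank 1
  expect_equal(rank_by_tss_proximity(cand[1, ], 1000L)$rank, 1L)

  # identical distance, strands + and -: + first, under both input orders
  tie <- cand
  tie$strand <- c("-", "+")
  tie$start <- c(700L, 700L); tie$end <- c(719L, 719L)
  for (ord in list(1:2, 2:1)) {
    r <- rank_by_tss_proximity(tie[ord, ], 1000L)
    expect_equal(r$strand, c("+", "-"))
  }
})

test_that("off-target filter removes cross-promoter matches unless grouped", {
  seq <- rand_dna(100)
  wins <- rbind(fake_window(seq, "G1", "G1_t"),
                fake_window(seq, "G2", "G2_t", start = 5001L))
  wins$contig <- c("chr1", "chr2")
  cands <- do.call(rbind, lapply(1:2, function(i)
    enumerate_protospacers(wins[i, , drop = FALSE])))
  expect_gt(nrow(cands), 0)

  # byte-identical promoters, no group: everything removed
  res <- offtarget_filter(cands, wins)
  expect_equal(nrow(res$kept), 0)
  expect_equal(nrow(res$removed), nrow(cands))

  # same windows declared a shared group: kept and annotated
  res2 <- offtarget_filter(cands, wins, shared_groups = list(c("G1", "G2")))
  expect_equal(nrow(res2$kept), nrow(cands))
  expect_true(all(res2$kept$offtarget_genes %in% c("G1", "G2")))

  # guide unique to its own window: kept with empty annotation
  w3 <- fake_window(rand_dna(100), "G3", "G3_t", start = 9001L)
  w3$contig <- "chr3"
  all_wins <- rbind(wins, w3)
  c3 <- enumerate_protospacers(w3)
  if (nrow(c3)) {
    res3 <- offtarget_filter(c3, all_wins)
    expect_equal(nrow(res3$kept), nrow(c3))
    expect_true(all(res3$kept$offtarget_genes == ""))
  }

  expect_error(offtarget_filter(cands, wins, shared_groups = list("NOPE")),
               "unknown gene")
})

test_that("quota selection: seven as far as possible, relax to two, prefix", {
  mk_pool <- function(n, tag) {
    if (n == 0) return(NULL)
    data.frame(gene_id = "G1", tss_id = "G1_t",
               spacer19 = vapply(seq_len(n), function(i) rand_spacer(), ""),
               strand = "+", contig = "c", start = seq_len(n) * 30L,
               end = seq_len(n) * 30L + 18L, pam = "TGG", gc_fraction = 0.5,
               distance_to_tss = seq_len(n) * 10, rank = seq_len(n),
               relaxations = tag, offtarget_genes = "",
               stringsAsFactors = FALSE)
  }
  set.seed(7)
  # 10 strict candidates: exactly 7 selected, ranks 1..7
  res <- select_guides_for_target(mk_pool(10, ""))
  expect_equal(nrow(res$selected), 7)
  expect_equal(res$selected$rank, 1:7)
  expect_null(res$warning)

  # 1 strict + 4 gc-relaxed: at least two guides, extras carry the flag
  res <- select_guides_for_target(mk_pool(1, ""), mk_pool(4, "gc_relaxed"))
  expect_gte(nrow(res$selected), 2)
  expect_equal(sum(res$selected$relaxations == "gc_relaxed"), 4)

  # nothing at any tier: empty selection plus warning record
  res <- select_guides_for_target(mk_pool(0, ""))
  expect_equal(nrow(res$selected), 0)
  expect_match(res$warning, "only 0 guide")

  # prefix property: shrinking the quota keeps a prefix of the selection
  strict <- mk_pool(5, ""); gcr <- mk_pool(4, "gc_relaxed")
  full <- select_guides_for_target(strict, gcr, quota = 7)$selected
  for (q in 1:6) {
    sub <- select_guides_for_target(strict, gcr, quota = q,
                                    min_guides = 1)$selected
    expect_identical(sub$spacer19, utils::head(full$spacer19, q))
  }
})

test_that("cloned spacer is G + spacer, unconditionally", {
  expect_equal(finalize_cloned_spacer("ACGTACGTACGTACGTACG"),
               "GACGTACGTACGTACGTACG")
  allg <- strrep("G", 19)
  expect_equal(finalize_cloned_spacer(allg), strrep("G", 20))
  expect_equal(nchar(finalize_cloned_spacer(allg)), 20)
  s <- replicate(20, rand_spacer())
  expect_identical(substring(finalize_cloned_spacer(s), 2), s)
  expect_error(finalize_cloned_spacer("ACGT"), "19 nt")
})

test_that("non-targeting controls respect the Hamming-distance contract", {
  set.seed(11)
  genome <- c(chr1 = strrep("ACGT", 50))

  # an exact genomic substring is rejected
  inside <- substr(genome, 10, 28)
  expect_error(select_nontargeting_controls(inside, genome, n = 1),
               "exhausted")

  # brute-force oracle agreement on a random pool
  pool <- replicate(40, rand_spacer())
  ok_oracle <- vapply(pool, function(s) naive_min_hamming(s, genome) > 2,
                      logical(1))
  n_ok <- sum(ok_oracle)
  ctrl <- select_nontargeting_controls(pool, genome, n = n_ok)
  expect_setequal(ctrl$spacer19, pool[ok_oracle])

  # asking for more than the acceptable pool errors with the count
  expect_error(select_nontargeting_controls(pool, genome, n = n_ok + 1),
               "exhausted")
})

test_that("library table round-trips and design is deterministic", {
  ref <- make_synthetic_reference(n_genes = 4, n_valid = 3,
                                  duplicate_pairs = list(c(1, 2)), seed = 5)
  tss <- select_tss(ref$genes, ref$cage_peaks, ref$transcripts)
  w <- promoter_windows(tss, ref$genome)
  lib <- design_guide_library(w, genome = ref$genome,
                              shared_groups = ref$family_groups,
                              n_controls = 3, seed = 2)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_guide_library(lib, f1)
  lib2 <- read_guide_library(f1)
  write_guide_library(lib2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(lib2$guides$spacer19, lib$guides$spacer19)
  expect_identical(lib2$controls$spacer19, lib$controls$spacer19)

  # byte-identical output for identical inputs and config
  lib3 <- design_guide_library(w, genome = ref$genome,
                               shared_groups = ref$family_groups,
                               n_controls = 3, seed = 2)
  f3 <- tempfile(fileext = ".tsv")
  write_guide_library(lib3, f3)
  expect_identical(readLines(f1), readLines(f3))

  # empty library still writes a valid header-only table
  empty <- build_guide_library(crisprascreen:::empty_candidates()[
    , , drop = FALSE])
  f0 <- tempfile(fileext = ".tsv")
  expect_silent(write_guide_library(empty, f0))
  expect_equal(length(readLines(f0)), 1L)
})

test_that("every emitted guide obeys the library invariants", {
  ref <- make_synthetic_reference(n_genes = 5, n_valid = 4, seed = 9)
  tss <- select_tss(ref$genes, ref$cage_peaks, ref$transcripts)
  w <- promoter_windows(tss, ref$genome)
  lib <- design_guide_library(w, genome = ref$genome)
  g <- lib$guides
  expect_true(all(nchar(g$spacer19) == 19))
  expect_true(all(nchar(g$cloned_spacer) == 20))
  expect_true(all(substr(g$cloned_spacer, 1, 1) == "G"))
  expect_false(any(grepl("GAAGAC|GTCTTC", g$spacer19)))
  expect_true(all(table(g$tss_id) <= 7))
  # post hoc off-target check: no spacer occurs in a foreign window
  for (i in seq_len(nrow(g))) {
    foreign <- w[w$gene_id != g$gene_id[i], ]
    hits <- vapply(foreign$sequence, function(s) {
      grepl(g$spacer19[i], s, fixed = TRUE) ||
        grepl(crisprascreen:::revcomp(g$spacer19[i]), s, fixed = TRUE)
    }, logical(1))
    expect_false(any(hits))
  }
})
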
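---
title: "Designing and analyzing pooled CRISPRa receptor-ligand screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analyzing pooled CRISPRa receptor-ligand screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprascreen)
```

# The problem

Finding the cell-surface receptor for a ligand, antibody or other binding
probe is hard: membrane receptors are difficult to solubilize in native
conformation and their extracellular interactions are often very weak.
A pooled gain-of-function strategy sidesteps both problems. A lentiviral
library of guide RNAs directs a nuclease-dead Cas9 activator (CRISPRa) to
the promoters of all genes encoding membrane proteins, so that each cell in
a large population overexpresses one candidate receptor from its endogenous
locus. Cells are stained with a highly avid fluorescent probe, the brightest
cells are collected by FACS, and the guides they carry — read out by short
(19 bp) sequencing — identify the receptor. `crisprascreen` implements the
computational side of this workflow end to end: guide library design,
synthesis/cloning oligo tooling, read counting and QC, gene-level
enrichment statistics, and a generative simulator used to validate the
statistics against known ground truth.

# Guide library design

## TSS selection

CRISPRa only works within a narrow window upstream of the transcription
start site, so TSS choice dominates design quality. `select_tss()` applies a
three-tier hierarchy per gene:

1. **CAGE tag clusters** (empirical TSS evidence): the two *broadest* peaks
   per gene are kept, for sensitivity to alternative transcripts; the TSS is
   the peak summit. Width ties are broken by higher tag count, then by the
   5'-most peak on the gene strand. The summit anchor (rather than a peak
   edge) was an open choice; the summit is where CAGE evidence concentrates,
   and the midpoint is substituted when no summit is annotated.
2. **"Principal" transcripts** (APPRIS-style annotation) for genes without
   CAGE support: all distinct TSS positions (configurable cap).
3. **RefSeq NM transcripts** as the last resort.

Tiers are never mixed within a gene. Genes with no source in any tier are
reported and skipped.

## Promoter windows

`promoter_windows()` extracts the region 450–50 bp upstream of each TSS.
The bounds are read as an inclusive coordinate range, giving 401-nt
windows — a conservative superset of the 400-nt reading, and configurable.
All coordinates in this package are 1-based inclusive with an explicit
strand, the native convention of R/Bioconductor containers and of GTF;
BED input is converted on read. Windows are clipped at contig ends and
flagged; a window entirely off-contig is an error.

## Enumeration, filters, ranking

Within each window, every 19-nt sequence immediately 5' of an NGG PAM is a
candidate (both strands; minus-strand sites appear as CCN on the plus
strand). Candidates are discarded when:

* GC fraction (computed exactly on the 19-mer, before the 5' G is added) is
  below 0.30 or above 0.75 — extremes impair guide activity;
* the spacer contains a run of more than 3 consecutive T — a Pol III
  terminator that would truncate the transcript;
* the cloned context `G + spacer` contains a BbsI recognition site
  (GAAGAC/GTCTTC on either strand). The scan includes the constant G
  preceding the spacer in the synthesis oligo: a spacer beginning with
  AAGAC or TCTTC completes a third recognition site against that G and
  would be destroyed during Golden-Gate assembly. This is deliberately a
  superset of scanning the bare 19-mer.

Survivors are ranked by proximity of the protospacer *midpoint* to the TSS
(the natural reading of "proximity"; a PAM-proximal-edge metric is
configurable), with ties broken by plus strand first, then sequence.

## Off-target removal and shared promoters

Guides are screened for exact matches (either orientation) against every
promoter window in the design — the search space that matters for a
promoter-targeted activation library; a genome-wide mode exists but is off
by default. A guide matching a foreign gene's window is removed unless all
genes involved belong to one shared-promoter group. Groups are the union of
user-declared families and automatically derived groups of genes whose
windows overlap genomically by at least 1 bp (bidirectional promoters);
"similar" but non-identical family promoters cannot be derived from
sequence alone and must be declared.

## Selection quota and relaxation

Up to seven guides are selected per TSS in rank order. When fewer than
seven strict survivors exist, the GC rule is relaxed first, then the polyT
rule, appending relaxed survivors in rank order until the quota or the pool
is exhausted; BbsI and off-target failures are never relaxed because they
break cloning and specificity rather than merely reducing activity.
Targets that end below two guides are emitted in full with a warning
record. Selection is a prefix of a fixed ranked list, so shrinking the
quota never changes which guides remain — a property the tests assert.
Every selected spacer receives an unconditional 5' G (efficient U6
initiation), giving the 20-nt cloned spacer.

## Non-targeting controls

Controls anchor the null in screen analysis. A candidate pool (a published
set, or a seeded random generator for synthetic genomes) is screened by
exhaustive Hamming search: a sequence is accepted only if no 19-mer window
of the genome, on either strand, is within 2 mismatches. The implementation
uses `Biostrings` mismatch-tolerant matching; the test-suite checks it
against a brute-force scan. BbsI-context sequences are skipped up front.

# Oligos and Golden-Gate cloning

Libraries are synthesized as 77-mer single-stranded oligos:
39-nt constant flank + N19 + 19-nt constant flank. Each flank carries one
inward-facing BbsI site; BbsI cuts outside its recognition sequence with a
(2/6) geometry, so digestion of the amplified double-stranded oligo
releases a 24-bp insert `CACCG + spacer` with 4-nt 5' overhangs CACC and
AAAC, ready for ligation into the BbsI-linearized expression vector.
`bbsi_digest()` implements the cut arithmetic generically (it locates the
sites and applies the offsets, rather than hard-coding the product), and
the printed 24-bp fragment validates the geometry. Individually cloned
guides are emitted as the equivalent annealed 24-mer pair. The
reconciliation between the "add a 5' G" rule and the `CACCG` flank — the
cloned 20-mer is exactly the digested insert after the CACC overhang — is
asserted in the tests.

# Counting and normalization

Screens are sequenced with a custom primer reading exactly the 19 variable
bases (the +1 G comes from the constant vector flank and is never
sequenced), so `count_reads()` matches the first 19 nt of each read
*exactly* against the library spacers by hash lookup; there is no mismatch
tolerance by default, matching standard pooled-screen counters. Assigned
plus unassigned reads always equal input reads, and counting is
order-independent. `normalize_total()` scales each sample to a common total
(counts per million by default) — depth is the only between-sample factor
the published analysis corrected for.

`library_complexity_stats()` quantifies representation: fraction of guides
detected, Gini coefficient, and the fraction of guides whose counts lie
within a 100-fold window below a high-percentile reference count (the
99.9th percentile by default). The exact definition behind the published
"89% within two orders of magnitude" figure is not stated, so the window
and reference are parameters rather than opinions; under the simulator's
defaults the statistic reproduces ~89% (see the acceptance script).

# Enrichment statistics

## Guide-level negative-binomial null

For each guide, the sorted-sample count is tested against a null centred on
its control (plasmid) abundance. With two or more control replicate
columns, a mean-variance function is fitted across guides:
`log(variance − mean)` is regressed on `log(mean)` over guides whose sample
variance exceeds their mean, giving
`variance(m) = m + exp(a + b log m)`, clamped at the Poisson floor. With a
single control column replicate variance is unavailable and the null falls
back to Poisson. The one-sided enrichment p-value is the upper discrete
tail `P(X >= treatment)`; only enrichment is tested because the screens are
positive selections. Control means are floored at a pseudocount of 1.

Two numerical points matter in practice. First, p-values are computed and
ranked on the **log scale**: enriched tails underflow double precision
(`~1e-308`) long before the ranking information is exhausted, and ranking
on the natural scale collapses all strong guides into one tie block.
Second, replicate treatments are combined per guide by the median of their
(log) p-values — robust and simple; Fisher combination is available.

## Gene-level alpha-RRA

Guides are converted to joint percentile ranks over the whole library
(non-targeting controls stay in the ranking pool but are never scored as a
gene). Ties — common at the floating-point floor — are broken by a seeded
random key assigned in guide-id order. The key is deliberately independent
of gene membership: any tie-break correlated with gene identity (guide ids
sort same-gene guides adjacently) hands tied guides of one gene consecutive
ranks and fabricates gene-level signal.

A guide is *selected* iff its p-value is below `alpha` (default 0.05). A
gene with k guides and ascending ranks r(1) <= ... <= r(k) scores

rho = min over selected j of  Beta CDF( r(j); j, k − j + 1 ),

i.e. the most surprising selected order statistic; a gene with nothing
selected scores 1. Significance comes from a permutation null: each draw
takes k of the n observed (rank, selected) pairs without replacement and
recomputes rho under the same rule. Because the observed percentiles are
exactly the grid {1/n..n/n} and selection is monotone in rank, this equals
sampling k grid points — which keeps the null independent of guide input
order and makes small instances agree exactly with exhaustive enumeration
over all C(n,k) assignments (a property the acceptance tests verify).
Draws are cached per guide-count class k and seeded per (seed, k);
p = (1 + #{null rho <= observed}) / (1 + n_perm).

Gene p-values are adjusted by Benjamini-Hochberg (`stats::p.adjust`), and
genes at FDR below 0.1 are the candidate receptor calls. Genes excluded
from an analysis (e.g. a contaminated gene or a spiked positive control)
are dropped *before* ranking: their inflated counts would otherwise distort
the joint rank pool, which is the reason for excluding them at all.

A structural note on calibration: for any `alpha < 1` the gene p-value law
has an atom at 1 (genes with no selected guide get rho = 1 on both the
observed and null side), so the p-value distribution under a global null is
uniform only on its continuous part. The calibration test therefore runs
with `alpha = 1` (plain rank aggregation), where the permutation p-values
are genuinely U(0,1); at 2,000 null genes the Kolmogorov-Smirnov statistic
is ~0.02.

`screen_test()` wires these stages together and returns a classed object
with `print`, `summary`, `plot` (rank vs -log10 p with FDR calls
highlighted, the figure style used for screen readouts) and
`as.data.frame` methods. Fixed seed in, byte-identical results out.

# The screen simulator

The simulator exists to test the analysis, and the designer, against known
truth. Its generative law mirrors the experimental design:

* **Plasmid representation**: log-normal guide abundances with
  `sdlog = 1.07`. This value is derived, not fitted: requiring that ~89% of
  guides fall within a 100-fold window below the 99.9th-percentile count
  gives `sigma = log(100) / (z[0.999] − z[0.11]) ≈ 1.07`.
* **Transduction**: each cell receives exactly one guide, multinomially by
  plasmid abundance — the intent of the low-MOI design (MOI 0.3; the MOI is
  carried in the config and the expected multiplicity among transduced
  cells is reported in the truth manifest, but multi-integration cells are
  not modeled).
* **Activation heterogeneity**: each *guide* is functional with probability
  `p_guide_active` (Bernoulli per guide, fixed by the seed); cells carrying
  a functional guide against a true hit gene add a log-normal
  surface-expression signal (meanlog 3, sdlog 1) on top of log-normal
  staining background (meanlog 0, sdlog 1). This reproduces the observed
  pattern that only a fraction of transduced cells upregulate, at widely
  varying levels, without claiming mechanistic fidelity; all knobs are
  config-exposed.
* **Sorting**: the brightest `sort_fraction` (default 5%) of cells are
  collected.
* **Sequencing**: plasmid, presort and sorted pools are read out by
  Dirichlet-multinomial draws (PCR jackpotting); the per-guide
  concentration default of 1000 gives mild overdispersion (~1.4x
  multinomial at desk scale). Column sums equal the configured depth
  exactly.

The default ("desk") profile is 1000 genes x 5 guides, 5 hit genes, 2e5
cells and 2e6 reads per sample — the same generative law as the published
screen scaled to laptop size; `default_paper_config("paper")` carries the
full-scale numbers (6213 genes, ~7 guides each, 1e8 cells, 5% gate).

`p_guide_active` defaults to 0.9. The package's own target for the desk
profile is that all five planted hits are recovered at FDR <= 0.1 in at
least 95% of independent replicates: recovery of a hit requires at least
two functional, adequately represented guides, and accounting for both
loss terms (inactive guides, Binom(5, p) <= 1; and rare-guide borderline
misses, ~15% of exactly-2-active genes) puts the per-gene failure at
~0.2% when p = 0.9. A library in which ~90% of designed guides are
functional is consistent with the published library's individual-guide
validation. Lower per-guide activity — as in early pilot designs — is a
config knob, not a different model.

What the simulator does **not** model: antibody affinity chemistry,
cytometer optics, cell growth or dropout during culture, untransduced
cells (removed experimentally by BFP sorting), and multi-guide cells.
Passing the end-to-end tests therefore shows that the statistics recover
truth under this generative law, not that any particular wet-lab screen
will behave as simulated.

# Numerical choices and degenerate inputs

* Discrete tails use `ceiling(t) − 1` on normalized (real-valued) counts,
  so a treatment count of 0 gives p = 1 exactly.
* The mean-variance regression needs >= 10 usable guides; otherwise it
  falls back to Poisson with a warning.
* Windows shorter than 22 nt enumerate nothing (with a warning); a
  zero-total sample is an error naming the sample; a gene with zero guides
  in the rank test is an error.
* `n_perm` defaults to 10,000, putting the smallest attainable gene
  p-value at ~1e-4 — small enough for FDR < 0.1 calls at 1000-gene scale.
  Tests use 1,000 where only calibration shape matters.
* All randomness flows from explicit seeds through a single helper that
  restores the caller's RNG state; identical inputs and seeds give
  byte-identical outputs, including serialized tables.

# Problem sizes used by the checks

The test-suite and `scripts/acceptance.R` run at desk scale: 200 random
windows for the designer-vs-oracle property, exhaustive permutation
oracles up to 8 guides, 2,000 genes for the calibration KS check, 10,000
guides for the representation QC, and 20 independent end-to-end simulated
screens (1000 genes x 5 guides each) for hit recovery. These sizes were
chosen so that the whole validation runs comfortably on a laptop while
keeping every estimate's Monte-Carlo error well inside the asserted
margins.

# Known limitations

* Exact numeric agreement with any particular MAGeCK release is not a
  goal; the analysis reimplements the described algorithm (NB guide null,
  modified RRA, BH FDR), and concordance is expected at the level of
  FDR < 0.1 calls.
* The designer's off-target screen is exact-match over promoter windows,
  as in the original design procedure; it is not a genome-wide activity or
  specificity model, and no on-target efficacy score is computed.
* The reanalysis of the published raw-count supplement requires that
  spreadsheet to be exported as TSV and placed at
  `inst/extdata/published_screen_counts.tsv`; it is not redistributed with
  the package.
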
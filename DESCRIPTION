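Package: crisprascreen
Title: Design and Analysis of Pooled CRISPR-Activation Receptor-Ligand Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled CRISPR-activation (CRISPRa) screens that identify
    cell-surface receptors for ligand or antibody probes by FACS enrichment.
    Covers promoter-targeted guide library design (CAGE/APPRIS/RefSeq TSS
    hierarchy, 450-50 bp promoter windows, NGG protospacer enumeration with
    GC/polyT/BbsI filters, TSS-proximity ranking, promoter-wide exact
    off-target removal, seven-guide quotas with rule relaxation, non-targeting
    controls), Golden-Gate synthesis oligo tooling with in-silico BbsI
    digestion, read counting and normalization of guide count tables,
    gene-level enrichment testing (negative-binomial guide statistics, modified
    robust rank aggregation with a permutation null, Benjamini-Hochberg FDR),
    and a generative simulator of sort-gate enrichment screens with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
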
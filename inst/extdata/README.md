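# extdata

`published_screen_counts.tsv` (not redistributed): the raw guide read
counts of the published screens, exported from the journal's supplementary
spreadsheet as tab-separated text with columns `sgRNA`, `gene`, `plasmid`,
`d7`, `d12-transduced`, `8aB_rep1..3`, and one column per protein probe.
Placing it here enables the reanalysis test in
`tests/testthat/test-acceptance.R`.
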
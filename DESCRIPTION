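Package: sparsemeth
Title: Tumour Classification from Sparse Nanopore Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains, calibrates and evaluates a neural-network classifier of
    central nervous system tumour types from very sparse CpG methylation
    profiles, of the kind produced by short intraoperative nanopore sequencing
    runs. Sparse runs are simulated from methylation-array beta values
    (binarization, read placement, coverage noise), the classifier is trained
    with a curriculum over sparsity levels and adaptive class-by-sparsity
    balancing, and scores are calibrated by temperature scaling. Also provides
    the surrounding intraoperative machinery: windowed majority-vote mapping of
    per-read methylation calls onto array probes, pseudotime from cumulative
    CpG call counts, purity and read-order robustness sweeps, adaptive-sampling
    target-region design, and simplified shallow-coverage copy-number profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
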
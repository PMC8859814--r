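Package: chicbench
Title: Benchmarking Toolkit for Capture Hi-C Interaction Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating Capture Hi-C (CHi-C) interaction callers
    at restriction-fragment resolution: in-silico genome digestion and
    CHiCAGO-style rmap/baitmap handling, bait-probe eligibility under
    capture design constraints, a self-contained binomial random-ligation
    background caller with Benjamini-Hochberg correction, per-bait local
    filtering of significant interactions via the elbow of the cumulative
    -log10(q) curve, replicate-reproducibility and joint-mean threshold
    metrics, functional overlap with chromatin peak tracks, and a fully
    deterministic synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
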
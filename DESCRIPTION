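Package: tadakit
Title: Lineage-Resolved Targeted DamID and Chromatin Accessibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for Targeted DamID (TaDa) and Dam-only
    chromatin accessibility (CaTaDa) profiling at GATC-fragment resolution.
    Builds the GATC fragment coordinate system from a genome, extends and
    counts aligned reads, computes decile-exclusion normalized
    log2(fusion/Dam) ratio tracks, calls bound and accessible regions with a
    transparent Poisson model, tests differential occupancy between two cell
    lineages with a negative-binomial Wald test on a consensus-peak affinity
    matrix, and provides Monte Carlo interval statistics (randomized
    peaksets preserving per-chromosome peak counts and lengths, overlap and
    signal-ratio tests, closest-peak Fisher tests), reference-point signal
    metaprofiles and replicate correlation. Includes a synthetic-data
    generator encoding the open-chromatin-gates-binding model so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
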
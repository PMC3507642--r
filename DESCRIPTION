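Package: cistromedose
Title: Dose-Dependent Cistrome Comparison for Nuclear Receptor Antagonists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how small-molecule antagonism reshapes a
    transcription factor's genome-wide binding landscape (cistrome) across a
    dose series, and for integrating binding impact with differential gene
    expression to classify direct activation and repression targets.
    Provides high-confidence peak filtering against swapped-channel negative
    peaks, robust per-site signal quantification with the one-step Tukey
    biweight, a percent-impact dose metric over differentially occupied
    sites, summit-anchored sequence-conservation profiling, position weight
    matrix scanning with matched-background specificity Z-scores and
    element-pair spacing statistics, hypergeometric gene-signature
    enrichment with Storey q-values, and a synthetic-data generator that
    emits complete dose-series experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
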
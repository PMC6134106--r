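Package: mitohet
Title: Mitochondrial Point Heteroplasmy: Simulation, Calling and Population Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying low-frequency point heteroplasmy in circular
    mitochondrial genomes. Provides a count-level pileup simulator with planted
    low-frequency variants, an exact-binomial heteroplasmy caller with
    circular-reference handling and the standard minor-allele-frequency and
    coverage filters, a caller benchmarking framework (power, accuracy, false
    positive rate and a composite score over a coverage grid), sample-level
    quality-control filters, mutation-spectrum and coding-effect
    characterisation under the vertebrate mitochondrial code, and an inference
    chain for age association of heteroplasmy counts (negative binomial GLM,
    Cook's influence diagnostics, bootstrap, recapture-choice permutation) plus
    longitudinal summaries of heteroplasmy dynamics in recaptured individuals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
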
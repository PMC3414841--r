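Package: mutforge
Title: Mutational Process Analysis for Somatic Mutation Catalogs
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for dissecting the mutational processes recorded in
    whole-genome somatic mutation catalogs. Builds 96-channel
    trinucleotide-context substitution spectra, extracts mutational
    signatures by nonnegative matrix factorization with cophenetic
    model selection, detects regional hypermutation (kataegis) from
    intermutation distances, tests double-nucleotide substitutions for
    enrichment over chance adjacency by Monte Carlo simulation,
    quantifies transcriptional strand bias and expression-related
    mutation prevalence, and classifies small deletions as
    tandem-repeat- or microhomology-mediated. Includes a synthetic
    catalog generator with full ground truth for validating every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: SomaticMutation, StatisticalMethod, Software
RoxygenNote: 7.3.3
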
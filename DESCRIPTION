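Package: epiclonal
Title: Somatic Mutation Selection and Clonality Analysis for Deep Targeted
    Sequencing of Normal Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic mutation calls from deep targeted
    sequencing of normal tissues such as sun-exposed skin and oral epithelium.
    Implements context-normalized dN/dS selection statistics over the 96
    pyrimidine-centered trinucleotide substitution classes with one-sided
    binomial tests and Benjamini-Hochberg correction, a functional impact
    score selection test against a simulated per-gene null, clone size and
    tissue occupancy inference from variant allele frequencies, UV-specific
    spectrum analyses (dipyrimidine context, transcriptional strand bias,
    CC>TT dinucleotide variants, signature refitting), and barcode-family
    consensus calling for ultra-sensitive hotspot quantification. A synthetic
    data generator produces every input format the pipeline consumes so all
    stages can be exercised without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    pracma,
    stats,
    utils
Suggests:
    GenomicRanges,
    jsonlite,
    seqinr,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
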
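Package: rnafidelity
Title: Transcription Error Rates from RNA-seq Mismatches and RNA
    Polymerase Proofreading Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates in vivo transcription error rates from RNA-seq
    alignments using a position-wise, substitution-specific mismatch
    statistic with Phred-quality thresholding and exclusion of genomic
    single-base variants, and fits the enzyme-kinetics models used to
    characterise RNA polymerase proofreading: single-exponential
    time courses, Michaelis-Menten magnesium dependence, Arrhenius
    activation energies and pH-rate profiles (log-linear versus
    titration with an apparent pKa). A synthetic-data module generates
    reference genomes, strand-specific reads carrying independently
    controlled transcription-error, sequencing-error and variant
    channels with full truth tables, and noisy kinetic series, so that
    every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    Rsamtools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, Sequencing, Alignment, QualityControl
RoxygenNote: 7.3.3
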
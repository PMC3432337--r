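Package: dmhmix
Title: Empirical Bayes Mixture Models for Two-Color Differential
    Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits five empirical Bayes two-component mixture models
    (gamma-gamma and log-normal-normal hierarchies, with optional
    replicate- and pixel-level noise layers) to probe-level signals from
    two-color differential methylation hybridization (DMH) arrays.
    Includes probe signal and standard-error extraction from
    GenePix-style tables, lowess M-A normalization with consistent
    standard-error rescaling, an EM fitter with numerical M-steps and
    per-probe variance hill climbing, posterior classification of
    differentially methylated loci, time-dependent methylation-pattern
    categorization across cell generations, transcription factor
    binding site enrichment against GC- and length-matched background
    sequences, and generative simulators for all five hierarchies with
    a true/false positive rate study for the log-normal model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
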
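Package: salmoquant
Title: Quantification of Rainbow Trout Adulteration in Atlantic Salmon by
    Duplex Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the absolute quantification of rainbow trout
    (Oncorhynchus mykiss) adulteration in Atlantic salmon (Salmo salar)
    products from duplex droplet digital PCR (ddPCR) droplet counts.
    Implements Poisson inversion of droplet positive/negative counts into
    copies per microlitre with Wilson-score confidence intervals,
    calibration of the transfer coefficient K that converts myoglobin-gene
    copy-number ratios into meat mass ratios, the one-step mass-fraction
    formula M_O/M_S = K * Q_O/Q_S, method-validation procedures (dynamic
    range regression, limit of detection and quantification decision rules,
    repeatability/reproducibility summaries, one-way ANOVA for treatment
    effects), a qPCR standard-curve comparator pipeline, in-silico PCR
    specificity checking of primer/probe sets, and a seeded synthetic
    duplex-ddPCR data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
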
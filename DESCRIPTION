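Package: tetradose
Title: Allele Dosage Calling for Tetraploids from Bi-Allelic Marker Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns allele dosages (0-4) to tetraploid samples for bi-allelic
    markers from two-channel assay intensities (e.g. Illumina GoldenGate
    exports). Fits five-component Gaussian mixture models to arcsine-square-root
    transformed allele signal ratios, with component means constrained by
    parametric dosage-response models and, optionally, mixing proportions
    constrained to Hardy-Weinberg equilibrium ratios. Eight model variants are
    fitted per marker by an EM algorithm with a weighted nonlinear
    least-squares M-step, started from multiple configurations, and the best
    fit is selected by BIC. Markers with unreliable signal distributions are
    rejected by intensity-coverage, call-fraction, dispersion and
    peak-dominance filters, and samples without a confident posterior are left
    uncalled. Includes a ground-truth simulator for two-channel assay data,
    tabular and graphical reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
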
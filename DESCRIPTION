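Package: siascore
Title: Immune Activation Scoring from Multiplex IHC and RNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end quantification of the tumour immune
    microenvironment from per-cell multiplex immunohistochemistry marker
    intensities. Determines marker positivity thresholds by kernel density
    estimation, classifies cells into immune classes, computes
    area-normalised cell densities, and derives the Signature of Immune
    Activation (SIA; the ratio of CD8+ cell density to the sum of CD8+ and
    CD68+CD163+ macrophage densities) together with an Immunoscore-like
    mean-percentile metric. Provides survival analytics (Kaplan-Meier,
    Cox proportional hazards, bootstrap and time-dependent AUC, Wald
    chi-square contribution decomposition, optimal-cutoff
    dichotomisation), RNA-level SIA surrogates from bulk (CD8A/C1Q ratio)
    and single-cell (marker-positive cell counting) expression, a
    tile-resampling Kolmogorov-Smirnov test of tissue-microarray
    representativeness, and a synthetic-data generator that emulates every
    input so the whole pipeline is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    survival,
    Matrix,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
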
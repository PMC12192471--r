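Package: ctnps
Title: Frequency-Resolved Noise Analysis for Repeated CT Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising computed-tomography image noise in the
    frequency domain. Estimates two-dimensional noise power spectra (NPS) from
    ensembles of repeated reconstructions via the difference-image method,
    reduces them to one-dimensional curves by directional sampling and angular
    averaging, and compares reconstruction algorithms band-wise with crossover
    detection. Ships a seed-controlled synthetic generator of CT noise
    ensembles with filtered-back-projection-like and iterative-reconstruction-
    like textures and quantum-noise dose scaling, plus the accompanying
    statistical battery for regions-of-interest Hounsfield-unit tables and
    ordinal image-quality scores (normality and homoscedasticity screening,
    one-way and repeated-measures ANOVA with Greenhouse-Geisser correction,
    Bonferroni pairwise comparisons, paired t and Wilcoxon signed-rank tests)
    and effective-dose bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
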
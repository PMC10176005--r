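Package: qmritrack
Title: Longitudinal Quantitative MRI Analysis of Multiple Sclerosis Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking microstructural change in multiple sclerosis
    brain from multiparameter mapping (MPM) data. Estimates MTsat, PD, R1 and
    R2* maps from multi-echo FLASH series via a joint (ESTATICS-style) R2*
    fit and small-flip-angle closed forms, turns tissue posterior probability
    maps and FLAIR lesion masks into exclusive tissue and lesion-periphery
    areas, computes brain volume fractions and their annualized changes,
    scores disease activity with the NEDA-3 composite rule, performs
    permutation inference with FDR control on annual rates of change of
    median parameter values in normal-appearing tissues, and compares lesion
    areas over time with a random-intercept mixed model and Tukey-adjusted
    contrasts. A seeded synthetic two-timepoint phantom cohort with known
    ground truth exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    pbkrtest,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
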
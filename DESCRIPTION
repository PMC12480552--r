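Package: msikp
Title: Quantitative MALDI Mass Spectrometry Imaging and Brain Partition
    Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative MALDI mass spectrometry imaging (MSI) of
    small-molecule drugs in brain tissue and for blood-brain-barrier partition
    pharmacokinetics. Implements mimetic-tissue-model calibration with limit of
    blank and limit of detection estimation, the conditional pixel-by-pixel
    internal-standard normalization rule, per-pixel back-calculation to tissue
    concentration, region-of-interest summaries, unbound partition coefficients
    (Kp brain, Kp,uu brain, Kp tumor) with explicit aggregation and
    below-quantification-limit policies, Welch tests and nested mixed-effects
    models with estimated marginal means on regional concentrations, and a
    seeded synthetic-study generator so that the entire workflow is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    png,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
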
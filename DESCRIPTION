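Package: glymphalps
Title: Diffusion-Tensor ALPS Index Pipeline with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the diffusion tensor
    imaging "analysis along the perivascular space" (DTI-ALPS) index, an
    indirect MRI marker of glymphatic function. Provides a digital
    diffusion-MRI phantom with projection/association fiber geometry and
    Rician noise, log-linear least-squares tensor estimation with
    background-noise brain masking, ROI-based ALPS index computation, a
    two-group synthetic cohort generator with clinical covariates, and the
    accompanying statistical layer (t-tests, chi-square, ANCOVA with
    covariates, Cohen's d and f effect sizes, Bonferroni correction,
    Pearson and partial correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
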
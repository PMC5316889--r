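Package: painsig
Title: Stimulus-Intensity-Independent Pain Signatures from Trial-Level Brain Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and applying multivariate brain signatures of
    pain that are independent of noxious stimulus intensity. Implements
    single-trial (beta-series) GLM estimation with variance-inflation-factor
    trial exclusion and slice-statistic spike detection, per-subject
    residualization against stimulus-intensity indicators and a reference
    nociceptive signature, principal component regression decoders with
    cross-validated precision weights, precision-weighted group aggregation
    with weighted t-statistics, FDR thresholding and contiguous region
    extraction, signature scoring (global and local pattern expression),
    leave-one-subject-out evaluation, and multilevel GLM and mediation
    inference with bootstrap and permutation tests. A synthetic-data module
    generates multi-subject trial-level datasets and BOLD runs with planted
    ground truth so every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
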
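Package: gbsi
Title: Generalized Boundary Shift Integral for Longitudinal Atrophy Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures longitudinal volume change of the brain and of small
    structures such as the hippocampus from pairs of co-registered T1-weighted
    MRI volumes with probabilistic segmentations. Implements the generalized
    boundary shift integral (gBSI), whose boundary region is a probabilistic
    exclusive-OR of the two time points' segmentations rescaled by an adaptive
    gain factor, together with the classic binary-XOR (KN-BSI) and fuzzy
    (pBSI) region variants, k-means tissue intensity normalization, automatic
    single and double intensity-window selection, symmetric differential bias
    correction, annualized percentage volume change, clinical-trial sample-size
    estimation with bias-corrected bootstrap confidence intervals, and a
    synthetic ellipsoid phantom generator with analytically known volume change.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
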
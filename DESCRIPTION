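Package: relb1map
Title: Large Dynamic Range Relative B1+ Mapping for Parallel-Transmit MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs relative transmit-field (B1+) maps for
    parallel-transmit MRI from spoiled-gradient-echo (SPGR) images acquired
    at multiple radiofrequency drive levels per transmit channel. Each voxel
    is combined across drive levels by a closed-form maximum-likelihood
    estimator that automatically rejects measurements saturated beyond the
    low-flip-angle regime, yielding complex per-channel images proportional
    to the transmit sensitivity. Includes RF drive-scheme design from a
    linearity tolerance, relative magnitude and phase map formation, a
    synthetic multi-channel phantom generator with known ground truth, a
    Monte Carlo error-characterisation study, and NIfTI input/output with
    JSON sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
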
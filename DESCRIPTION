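Package: lcnbm
Title: Locus Coeruleus Signal Intensity and Nucleus Basalis of Meynert
    Volumetry from Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the combined in vivo MRI assessment of locus
    coeruleus (LC) integrity and nucleus basalis of Meynert (NBM) volume.
    Extracts a normalized LC signal intensity (LC-I) from turbo-spin-echo
    slabs by a deterministic top-k brightest connected-voxel search inside
    template-defined bounding boxes, computes native-space NBM volumes by
    warping an atlas mask through subject-specific spatial transforms,
    builds composite cortical volumes-of-interest from regional statistics
    tables, and runs the accompanying statistical plan (ANCOVA group
    comparisons with age and sex covariates, partial correlations with
    categorical covariates, Bonferroni families). A phantom generator
    produces synthetic subjects with known ground truth so that every
    stage supports parameter-recovery and error-rate testing without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
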
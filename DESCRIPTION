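Package: petresp
Title: Metabolic Tumor Response Classification from FDG-PET (PERCIST and EORTC)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies FDG-PET lesion uptake (SUVmax, SUVmean, SUVpeak,
    SULpeak, metabolic tumor volume and total lesion glycolysis) from voxel
    volumes or lesion-level tables, screens scan pairs for measurability and
    liver-reference comparability, applies four metabolic response rule sets
    (PERCIST 1.0, mPERCIST, PERCISTmax and EORTC) under hottest-lesion or
    all-lesions target selection, dichotomizes patients into disease control
    versus progressive disease, and compares the groups with Kaplan-Meier
    estimates, Monte-Carlo permutation log-rank tests and bootstrap t-tests.
    Ships a synthetic longitudinal cohort and phantom generator so the whole
    pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
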
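Package: deltarad
Title: Delta-Radiomics Texture Analysis and Survival Modelling for Longitudinal CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delta-radiomics analysis of paired (pre- and
    post-treatment) CT scans of liver lesions: intratumoral and fat-excluded
    peritumoral region construction, slice-wise texture response maps
    (local Haralick gray-level co-occurrence statistics, Laws and
    Laws-Laplacian kernels, Gabor filter banks) summarised by first-order
    statistics, 3D shape descriptors, z-score normalisation and
    post-minus-pre feature deltas, a LASSO-Cox radiomic risk score with
    Kaplan-Meier, log-rank and concordance evaluation, clinical nomogram
    construction with bootstrap calibration and decision-curve analysis,
    and a linear-discriminant response classifier. Includes a synthetic
    CT phantom cohort generator with planted texture-change effects so
    the whole pipeline can be exercised and validated without patient
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
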
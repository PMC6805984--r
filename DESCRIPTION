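Package: pcrvol
Title: Volumetric Tumor Shape Features and Prediction of Pathological
    Complete Response in Rectal Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes shell-based volumetric imaging parameters
    (approximate and real tumor volume, inner/outer 1-mm shell surface
    surrogates, tumor compactness, maximum longitudinal length and
    transverse diameter) from paired 3D tumor and lumen segmentation
    masks with anisotropic voxel spacing, codes them into ordinal
    clinical strata, and models pathological complete response after
    preoperative chemoradiotherapy in locally advanced rectal cancer by
    univariate and forward-stepwise multivariate logistic regression
    with collinearity screening, Hosmer-Lemeshow calibration and ROC
    cutoff analysis. Includes frozen published prediction equations, a
    synthetic voxel-phantom cohort simulator for end-to-end validation,
    and NIfTI import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    car
biocViews: Software, StatisticalMethod, Classification, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
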
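Package: voxfract
Title: 3D Box-Counting Fractal Dimension and Lacunarity from Binary Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional box-counting fractal dimension,
    gliding-box lacunarity, sphericity, maximum diameter, and volume from
    binary tumour segmentation masks (NIfTI), and provides the accompanying
    radiogenomic statistical pipeline: normality-routed group comparisons,
    univariable and multivariable logistic modelling with backward
    likelihood-ratio elimination and collinearity screening, ROC analysis
    with bootstrap confidence intervals, and interrater agreement (Cohen's
    kappa, two-way intraclass correlation). Includes generators for
    geometric phantoms with known fractal properties (cubes, slabs, balls,
    Menger sponges, perturbed blobs) and for synthetic patient cohorts, so
    the full pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
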
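Package: dceqc
Title: Explainable Radiomics-Based Image Quality Assessment for Breast DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: No-reference image quality assessment for dynamic contrast-enhanced
    breast MRI. Samples slices from a 3D volume, locates anatomy-free background
    regions in image corners by a signal-to-noise criterion, extracts an
    821-dimensional dual-ROI feature set (IBSI-style first-order and texture
    features over an original/wavelet/Laplacian-of-Gaussian filter bank, plus
    BRISQUE and total-variation metrics), selects features by a
    variance/ANOVA/L1-logistic cascade, classifies high versus low quality with
    patient-stratified cross-validation and per-patient soft voting, and
    explains model decisions with Shapley-value attributions. Includes a
    synthetic MRI phantom generator with controllable noise, blur, stripe and
    ghosting artifacts so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    glmnet,
    e1071,
    randomForest,
    class,
    rpart,
    pROC,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
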
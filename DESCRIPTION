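Package: mismatchnet
Title: Group-Equivariant Deep Learning for DWI-FLAIR Mismatch Stroke Onset Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts dichotomized stroke onset time (within 4.5 hours versus
    later) from paired diffusion-weighted (DWI) and fluid-attenuated inversion
    recovery (FLAIR) MRI volumes using 3D convolutional networks that are
    equivariant to the D4h point group (16 orientations), with optional
    convolutional-autoencoder pre-training and autoencoder-regularized
    training. Includes the full evaluation framework (ROC/AUC, Youden and
    sensitivity-calibrated thresholds, indeterminable-rating handling,
    human-rating augmentation, Cohen's kappa, bootstrap plus Wilcoxon
    signed-rank testing), SmoothGrad saliency with automated localization
    scoring, NIfTI preprocessing, and a synthetic DWI/FLAIR phantom and
    synthetic-rater generator so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
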
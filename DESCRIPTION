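Package: strokenet
Title: Voxel-Wise Prediction of Chronic Stroke Lesions from Acute
    Multi-Parametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the 3-month T2-weighted MRI appearance of ischemic
    stroke lesions, voxel by voxel, from four co-registered acute-phase MRI
    contrasts (DWI, T1WI, T2WI, PDWI) using a small feed-forward neural
    network trained by batch back-propagation. Implements the full analysis
    pipeline: 3x3 unity-filter smoothing, brain-mean intensity
    normalization, lesion/contralateral ROI definition by chronic-T2
    thresholding and midline reflection, patient-level leave-one-out
    cross-validation with a correct-classification-fraction (CCF) plateau
    stopping rule, AUCCF-based architecture selection, ROC/AUROC and
    half-angle operating-point statistics, and cluster-robust correlation
    between predicted and observed outcome maps. Includes a synthetic
    multi-parametric MRI phantom generator so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
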
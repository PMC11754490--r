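Package: cacscore
Title: Automated Coronary Artery Calcium Scoring on Non-Gated Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully automated pipeline for detecting, quantifying and
    risk-categorizing coronary artery calcium (CAC) on non-ECG-gated
    chest CT. Reads DICOM series and NIfTI volumes, segments heart,
    aorta and epicardial fat with a pluggable backend (a built-in
    density/geometry reference backend works on digital phantoms;
    external model masks can be injected from files), splits the heart
    into AORTA/RCA/LAD/LCX territories from the aorta's axial shape
    progression, runs a calcium-candidate cascade (130 HU threshold, 2D
    morphological noise suppression, volume and peak-intensity filters,
    bone elimination by 3D dilation of large components,
    connected-component recovery, cardiac masking), computes per-artery
    and total Agatston scores with CAC-DRS grading, and evaluates
    agreement against reference scores (Cohen's kappa, per-category
    sensitivity/specificity/PPV/NPV/F1, confusion matrices, Dice). A
    synthetic chest-CT phantom generator with analytic ground-truth
    Agatston scores provides a fully controlled test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
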
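Package: IEFquant
Title: Densitometric Quantification and Detection Evaluation for Hemoglobin IEF Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for marker-free quantification of hemoglobin bands in
    isoelectric focusing (IEF) gel images. Provides box-based densitometry
    with background-threshold removal and relative-content computation
    (including the 3.5% Hb A2 screening rule), a classical profile-analysis
    band detector (projection, baseline correction, lane segmentation, peak
    detection, pI calibration), from-scratch bounding-box detection metrics
    (IoU, CIoU, average precision, mAP50, confusion matrix), Bland-Altman and
    regression method-agreement statistics, and a deterministic synthetic
    mIEF gel simulator with ground-truth annotations so the whole pipeline is
    testable without clinical data. Band annotations and external detector
    outputs are exchanged via YOLO-txt and JSON formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic-gel.R'
    'gel-io.R'
    'profile-detection.R'
    'band-quantification.R'
    'detection-eval.R'
    'agreement-stats.R'
    'pipeline.R'
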
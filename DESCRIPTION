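Package: faleak
Title: Semi-Automated Quantification of Fluorescein Angiography Leakage
    in Branch Retinal Vein Occlusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies vascular leakage on paired early (1-min) and late
    (5-min) fluorescein angiography frames of eyes with branch retinal vein
    occlusion. Frames are rigidly aligned, background-corrected with a
    rolling-ball filter, cropped around the fovea, auto-thresholded with the
    iterative intermeans (IsoData "default") method, and subtracted to form a
    binary leakage map; leakage severity is the mean gray value of that map
    over nested parafoveal (120 px) and perifoveal (240 px) windows. The
    package also provides the companion statistical toolkit (Mann-Whitney
    AUC with DeLong variance and paired tests, intraclass correlation for
    dual-grader agreement, backward stepwise logistic regression) and
    synthetic image/cohort generators with known ground truth so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
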
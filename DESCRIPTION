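Package: ki67roi
Title: Ki-67 Proliferation Index Estimation with Fuzzy Tumor-Cluster ROI
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the Ki-67 proliferation index (PI) of breast
    carcinoma immunohistochemistry (IHC) images. Tumor-cell-cluster
    regions of interest are detected by a fuzzy interpretation of
    overlapping sliding-window fragment classifications; within the
    defuzzified ROI, DAB and hematoxylin stains are separated by color
    deconvolution, thresholded by masked Otsu (optionally biased by
    reference thresholds from complementary training folds), cleaned
    morphologically, and the PI is approximated as the ratio of
    DAB-positive cell area to all relevant cell area. Includes a
    synthetic IHC slide generator with known ground truth, readers for
    ImageJ Cell Counter annotations, a compact CNN fragment classifier
    with majority-vote ensembling, and evaluation metrics (MAE, RMSE,
    bootstrap confidence intervals, invalid-estimation counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
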
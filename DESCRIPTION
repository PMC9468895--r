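Package: turstage
Title: Tumor-to-Uterus Area Ratio Staging of Early Endometrial Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for automatic FIGO IA/IB staging of early
    endometrial cancer from 2-D pelvic MRI slices. Provides a synthetic
    pelvic-phantom generator with paired ground-truth masks, LabelMe polygon
    annotation parsing and rasterization, a compact CPU-trainable U-net
    semantic segmenter (uterus / tumor / background), Dice similarity
    coefficient evaluation, the tumor-to-uterus area ratio (TUR) imaging
    biomarker, ROC analysis with Youden-index threshold selection, and
    k-of-n multi-sequence decision fusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
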
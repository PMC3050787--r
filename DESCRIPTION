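Package: perivasc
Title: Morphometric Analysis of Mobile-Cell Density Around Fixed Tissue
    Structures in Two-Color Immunohistochemistry Images
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of the relative density of mobile
    (e.g. immunostained leukocyte) cells within graded distance
    neighborhoods of fixed tissue structures (e.g. vascular endothelium)
    in two-color immunohistochemistry micrographs.  Implements
    relative-RGB-plane segmentation of red-stained cells and blue-stained
    structures, region-of-interest masking from polygon files, graded
    neighborhood construction by square-kernel morphological dilation,
    density fractions of the neighborhood and residual tissue, a
    random-cell simulation null model, patient-level summarization with
    exact paired Wilcoxon signed-rank testing, and a fully synthetic
    micrograph generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
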
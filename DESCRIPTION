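Package: lesionshape
Title: Morphometry of Ischemic Stroke Lesions and Association with Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the three-dimensional morphology of ischemic stroke
    lesions from binary masks in native voxel space (number of connected
    components, volume, mesh surface area, oriented minimum bounding box,
    fill ratio, and a sphere-normalized shape factor), classifies lesion
    location by atlas overlap (hemisphere, vascular territory, cortical
    involvement), and tests the association of lesion shape with newly
    detected atrial fibrillation using Mann-Whitney comparisons,
    Monte-Carlo chi-squared tests, and univariate, multivariate, and
    backward stepwise logistic regression. Includes ADC-threshold lesion
    segmentation and a synthetic-data module that generates lesion masks,
    ADC volumes, toy atlases, and cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
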
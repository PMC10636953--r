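Package: tangentfeat
Title: Tangential-Field Lung Exposure Features from CT Surface Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates normal-lung irradiation burden in breast-conserving
    radiotherapy from the two lead-wire skin markers visible on axial planning
    CT. Provides a seeded digital thorax phantom generator, lead-wire marker
    detection by heatmap regression (a compact multiresolution network trained
    with Adam on mean-squared heatmap error) alongside a classical high-density
    detector, distance-tolerance keypoint precision/recall metrics, the
    exposed ipsilateral-lung volume fraction defined by the marker line shifted
    5 mm toward the lung, a simplified tangential-beam dose simulator with
    dose-volume summaries (V20), and Pearson correlation reporting between the
    organ feature and simulated V20 across a cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
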
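Package: ihcthresh
Title: Locally Adaptive Threshold Segmentation Benchmark for DAB&H
    Immunohistochemistry Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for segmenting immunopositive (DAB-stained, brown) cell
    nuclei in brightfield immunohistochemistry images of lymphoma tissue and
    for benchmarking locally adaptive threshold algorithms against known
    ground truth. Provides three colour-separation transforms (blue channel,
    brown axis, colour deconvolution), six classic local threshold methods
    (Niblack, Sauvola, White, Bernsen, Yasuda, Palumbo) plus two
    Bernsen-contrast hybrids, a synthetic image generator that emulates
    DAB&H-stained tissue with exact nucleus templates and a microscope/camera
    degradation chain, and a pixel-, object- and shape-level evaluation
    framework including Bland-Altman agreement analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
biocViews: CellBiology, Software, Visualization
RoxygenNote: 7.3.3
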
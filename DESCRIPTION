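Package: spheromorph
Title: Quantitative Image Analysis of Epithelial Spheroid Rounding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how elongated epithelial cell masses round up
    into spheroids in time-lapse microscopy. Implements contour circularity
    (form factor) kinetics with latent/rising/static phase segmentation and
    fusion-jump detection, 3D nucleus detection by anisotropic
    difference-of-Gaussians filtering with nearest-neighbor trajectory
    linking, displacement-direction correlation of neighboring cell pairs,
    junction morphometrics (punctum adherens Feret diameters, tight-junction
    skeleton length), and spheroid-doublet fusion metrics (long-axis and
    contact length). A synthetic-data generator with exact ground truth makes
    every stage of the pipeline testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
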
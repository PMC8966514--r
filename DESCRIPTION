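Package: fociquant
Title: Quantification of Gamma-H2AX DNA Damage Foci from 3D Confocal and
    dSTORM Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify radiation-induced DNA double-strand-break
    repair foci marked by the phosphorylated histone gamma-H2AX. Implements
    the two complementary quantification branches used in radiobiology:
    (i) a 3D confocal branch with maximum-entropy foreground thresholding,
    26-connected voxel cluster extraction, watershed nucleus segmentation
    on the DAPI channel and per-nucleus foci counts, densities and volumes;
    and (ii) a single-molecule localization (dSTORM) branch with
    autocorrelation drift correction, DBSCAN cluster detection, convex-hull
    cluster areas, nearest-neighbor and radial density statistics, and
    epitope-number estimation through a fluorophore blinking model
    calibrated per field-of-view tile. Seeded synthetic-scene generators
    with full ground truth support end-to-end validation of both branches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
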
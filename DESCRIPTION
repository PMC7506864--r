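Package: canopyheight
Title: Grass Canopy Height Estimation from Before/After-Harvest Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates grass canopy height by differencing digital surface
    models (DSMs) rasterized from 3D point clouds acquired before and after
    harvest. Implements the four per-cell height-selection rules (maximum,
    average, minimum, and maximum-minimum), a resolution/method/sensor error
    sweep against ruler-style ground truth, and a synthetic canopy and sensor
    simulator (UAV structure-from-motion, pole-camera structure-from-motion,
    and hand-held LiDAR models) so the full pipeline is testable without
    field data. Reads and writes PLY, LAS 1.2, CSV point clouds and ESRI
    ASCII grid / single-band TIFF rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
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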
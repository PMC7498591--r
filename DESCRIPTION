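Package: smsep
Title: Single-Molecule On-Chip SDS-PAGE Separation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule protein separation in
    gel-embedded microfluidic channels imaged by widefield fluorescence video.
    Provides a ground-truthed synthetic video generator (labeled-protein plug
    injection, gel stacking, mass-dependent electrophoretic migration, gel-exit
    acceleration, EMCCD noise), Laplacian-of-Gaussian single-particle detection
    with subpixel centroids and intensity scoring, kymograph electropherograms,
    Gaussian band-stacking dynamics, double-count-free digital molecule
    counting, nearest-neighbour particle tracking with gel-exit velocity
    statistics, and semi-log molecular-weight versus mobility calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
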
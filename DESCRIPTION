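Package: retinaivm
Title: Longitudinal Intravital Retinal Imaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of longitudinal intravital two-photon
    imaging of the mouse retina in autoimmune uveoretinitis: synthetic
    retina phantoms with known ground truth, channel correction and
    vasculature-based session registration, 3D cell detection with
    concentric zonal infiltration statistics around the optic nerve head,
    track linking with motility and signed radial (centripetal vs
    centrifugal) displacement statistics, and ratiometric FRET calcium
    quantification with an anchored Hill calibration and a
    neuronal-dysfunction threshold.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
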
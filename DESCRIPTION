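Package: guvpore
Title: Pore Edge Tension from Electroporated Giant Vesicle Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated tracking of transient macropores in phase-contrast
    videos of giant unilamellar vesicles (GUVs) and estimation of the
    membrane pore edge tension from the slow, linear pore-closure regime,
    where R^2 ln r decreases linearly in time with slope -2*gamma/(3*pi*eta).
    Provides TIFF stack input/output and pre-processing (background
    subtraction, cropping, rotation, time slicing), per-frame membrane
    segmentation (Sobel gradient, isodata thresholding, speck removal,
    directional contour labeling), pore-width and vesicle-diameter
    measurement, linear-region detection and regression, a synthetic
    phase-contrast GUV video generator with ground truth for validation,
    and a headless analysis pipeline with tidy and ggplot2 accessors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    igraph,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
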
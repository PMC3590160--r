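Package: uavweeds
Title: UAV Mission Geometry, Band Alignment and Spectral Separability for
    Early-Season Weed Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning and evaluating unmanned-aerial-vehicle (UAV)
    imaging missions over row crops for early-season site-specific weed
    management. Computes photogrammetric mission geometry (ground sampling
    distance, image footprint, serpentine waypoint grids, image counts and
    flight duration) from camera optics and overlap settings; registers the
    channels of a multi-lens multispectral camera onto a master band via
    affine calibration with distance-dependent parallax correction and scores
    residual misalignment with spatial edge profiles; calibrates imagery
    against a reflectance panel, computes the NDVI, NGRDI and ExG vegetation
    indices and quantifies bare-soil/crop/weed class separability with
    one-way ANOVA plus LSD tests and the M-statistic; and generates synthetic
    multiband crop-field scenes with ground-truth class masks so the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    pracma
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
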
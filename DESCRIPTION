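Package: canopysphere
Title: Canopy Structure from Spherical Photography and Airborne Laser Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates forest canopy structure from 360-degree spherical
    photographs taken along vertical transects, for example from a small
    drone hovering inside a canopy gap. Equirectangular panoramas are
    reprojected to upward-looking hemispherical (fisheye-equivalent)
    images, segmented into sky and plant pixels by iterative isodata
    (Ridler-Calvard) thresholding after gamma linearization, and inverted
    to plant area index (PAI) through per-annulus gap fractions and the
    discretized Miller integral, with an optional shoot-clumping
    correction based on the silhouette-to-total-area ratio (STAR).
    Repeated measurements along a height transect yield vertical plant
    area density (PAD) profiles. A companion module derives a canopy
    transmission proxy from airborne laser scanning (ALS) point clouds,
    fits a Beer's-law extinction coefficient against the photographic PAI
    profile, and compares the two PAD profiles. Synthetic slab-canopy
    generators with closed-form gap fractions make every pipeline stage
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
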
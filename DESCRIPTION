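Package: spadspec
Title: Multispectral Plant Segmentation and SPAD Mapping for In-Field
    Spectral Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for processing 25-band snapshot-mosaic spectral image
    cubes of field crops: per-wavelength reflectance calibration against a
    four-level standard board, automatic plant segmentation with a modified
    difference vegetation index combined with Otsu thresholding and
    connected-domain labeling, chemometric SPAD (leaf greenness) modeling
    with SPXY sample partitioning, partial least squares regression and
    uninformative-variable elimination, and rendering of per-pixel SPAD
    distribution maps. Includes a seeded synthetic-scene generator so the
    full pipeline is testable without field data, and a command-line
    interface for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
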
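Package: uavweed
Title: Resampling Quality and Object-Based Weed Mapping for UAV Ortho-Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ultra-high-resolution UAV ortho-images of row crops with
    known ground truth, degrades them to coarser ground sample distances by
    nearest-neighbour resampling, classifies crop rows, weeds and bare soil
    with a three-step object-based image analysis (OBIA) procedure, and
    quantifies both the spatial quality of the resampled imagery (ASPRS 1990
    horizontal accuracy classes, band-histogram preservation) and the
    agronomic agreement of the resulting weed maps (per-frame weed cover,
    multi-threshold Treatment/No-Treatment maps and their concordance) for
    site-specific weed management.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
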
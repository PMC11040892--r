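Package: mncount
Title: Automated Micronucleus and Cell Scoring in Acridine Orange Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cytoplasm, nuclei and micronuclei in RGB fluorescence
    micrographs of acridine-orange stained cells and scores the in vitro
    micronucleus assay: total cells and micronucleated cells per image,
    micronucleus frequency, relative viability and method-comparison
    statistics per dose group. Segmentation follows a six-parameter model
    (binarization threshold, small and large morphological kernels, noise
    area cut, micronucleus circularity threshold and sigmoid window level)
    with erosion-based nucleus/micronucleus size discrimination and
    marker-controlled watershed separation of touching cells. Includes a
    seeded synthetic micrograph generator with exact ground truth, a
    reanalysis workflow driven by plain-text parameter files, and a
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
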
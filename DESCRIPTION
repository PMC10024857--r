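Package: chromoplex
Title: Cyclic Chromogenic Multiplex Immunohistochemistry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts iterative rounds of chromogenic brightfield
    immunohistochemistry (AEC/AMEC-red chromogen with hematoxylin
    counterstain) into a co-registered multi-channel pseudo-fluorescent
    stack, and quantifies the result: Beer-Lambert colour deconvolution
    into per-stain optical-density maps, counterstain-anchored
    round-to-round registration, de-staining and blocking quality control
    (residual area fractions), marker-combination phenotyping of
    microglia/macrophage objects, and distance-binned proximity of cell
    phenotypes to amyloid-plaque and tangle pathology. A ground-truthed
    synthetic brightfield scene generator makes every stage testable
    without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
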
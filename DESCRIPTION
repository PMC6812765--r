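Package: evnanoarray
Title: Morphometry of Individual Extracellular Vesicles on AFM Tethering Nanoarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM) height maps of
    extracellular vesicles (EVs) tethered on nanopatterned PEG-lipid brush
    arrays. Provides plane and scan-line leveling of height maps, segmentation
    and morphometry of dome-like particles (footprint diameter, apex height,
    aspect ratio), volume-conservation estimation of the suspension diameter,
    EV versus lipoprotein-like classification, the aspect-ratio power-law fit
    AR = c * d^-3, nanospot occupancy statistics, two-sample comparison of EV
    populations between cell lines, and a synthetic nanoarray scene generator
    with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    tiff,
    EBImage
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
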
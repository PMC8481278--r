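Package: fuccistage
Title: Interphase Cell-Cycle Staging of Single Nuclei from DAPI Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for staging interphase nuclei (G1 versus
    S/G2) in adherent-cell fluorescence microscopy. Ground-truth cell-cycle
    labels are derived automatically from two-channel Fucci2 reporter images
    (red Cdt1 reporter high in G1, green geminin reporter high in S/G2);
    nuclear area and integrated DAPI intensity are extracted per nucleus,
    z-scored per image, and fed to a class-weighted support vector machine
    with grid-searched kernels. Includes a classical baseline nucleus
    segmenter (Gaussian smoothing, Otsu threshold, optional watershed
    split), nested k-fold and leave-one-experiment-out cross-validation,
    and a seeded synthetic image generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
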
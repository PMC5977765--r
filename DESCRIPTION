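Package: poremorph
Title: Porosity Morphometry of Porous Membranes from Single SEM Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates the three-dimensional porosity of artificial porous
    membranes (e.g. tissue-engineering scaffolds) from single two-dimensional
    scanning electron microscope cross-section images. Provides discrete-geometry
    shape descriptors on pixel grids (4/8- and 6/26-connectivity, contour and
    surface counting measures, regularity coefficients for contours, ellipses and
    3D bodies), pore segmentation with per-pore 2D morphometry, a chord-based
    statistical volume-extension estimator that infers the invisible third pore
    axis from in-plane chord-length statistics under an isotropy assumption, a
    brightness-profile depth estimator mapping gray levels linearly to pore
    depth, specimen-level porosity summaries, and a seeded synthetic porous-scene
    generator with exact ground truth for validating every stage without real
    SEM data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
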
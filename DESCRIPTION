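Package: relrod
Title: Indexing and Geometry Refinement for Ultrafast Electron Diffraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinematical prediction, indexing and geometry refinement of
    single-crystal ultrafast electron diffraction (UED) patterns from
    imperfect quasi-single crystals. Bragg-spot positions and intensities
    are predicted under a Gaussian imperfection model (finite domain size,
    anisotropic mosaicity, beam divergence and energy bandwidth), matched
    to observed spots through disjoint circular ambits, and scored with a
    combined intensity-plus-position cost function. The crystal orientation
    is found by an exhaustive SO(3) search on a HEALPix-by-Psi grid and all
    model parameters are refined by bounded nonlinear least squares, with
    per-spot reflection-decomposition reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
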
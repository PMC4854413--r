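Package: rhoswitch
Title: Boolean Logic Modelling and Leading-Edge FRET Quantification of
    Rho GTPase Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the EGFR1-driven switch between Rac1 and
    RhoA activity at the leading edge of invasive cells. Provides a small
    Boolean logical-network engine (a line-oriented network format,
    AND/OR/NOT rule compilation with GEF/GAP precedence semantics for the
    Rac1 regulators, synchronous and random-asynchronous simulation,
    attractor and limit-cycle detection, and an in-silico knockout screen)
    together with a transcribed 41-node RCP/alpha5beta1/EGFR1 signalling
    network, and a semi-automated ratiometric FRET image pipeline
    (subpixel cross-correlation channel registration, a-trous wavelet
    band-pass segmentation, ring/crescent leading-edge regions of interest
    and mean-ratio timecourses) with seeded synthetic-data generators for
    both stages.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
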
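Package: phasorsnap
Title: Spectral Phasor Analysis for Sine/Cosine Filter Hyperspectral
    Snapshot Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and fit-free analysis of sine/cosine-filter
    hyperspectral snapshot fluorescence microscopy.  Provides the spectral
    phasor transform for filter triplets and multichannel spectral stacks,
    a forward model of the three-exposure acquisition with photon noise
    and camera artifacts, linear-combination unmixing (segment and
    triangle fractions, NADH/FAD optical redox ratio, dipolar relaxation
    index), phasor-plot polygon gating with image reciprocity,
    spectral-window mapping, per-slice profiles, and a command-line
    pipeline over multi-page TIFF stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
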
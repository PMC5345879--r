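Package: septrack
Title: Quantitative Analysis of Septal DNA Translocation in Bacterial
    Time-Lapse Microscopy
Version: 1.0.0
Authors@R: person("septrack", "developers", role = c("aut", "cre"),
    email = "septrack@example.org")
Description: Tools to quantify FtsK-mediated chromosome translocation across
    the closing division septum of asymmetrically dividing Escherichia coli
    from multi-channel time-lapse fluorescence movies. Extracts axial line
    profiles, tracks the constriction from phase contrast, partitions
    nucleoid-label intensity into the two daughter compartments, detects
    translocation start/end/pauses, converts intensity changes into DNA
    amounts and pumping speeds, measures Z-ring position/width/dissociation,
    and calibrates DNA amount against cell length. Ships a synthetic movie
    generator (rod-cell geometry, diffraction blur, shot noise, ground-truth
    traces) so every stage of the pipeline is testable without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
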
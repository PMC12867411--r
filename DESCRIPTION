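Package: nucflux
Title: Quantification of Passive Nuclear Transport Kinetics from
    Two-Channel Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses passive nuclear uptake of fluorescent
    cargo in permeabilized cells imaged as two-channel time lapses (a
    nuclear-stain frame at time zero plus a cargo channel over time).
    Provides a synthetic-data generator with full ground truth (elliptical
    nuclei, first-order saturating influx with rate set by pore count and
    per-pore unit diffusion, nuclear partitioning, photobleaching, shot and
    read noise), two-pass Otsu nucleus segmentation with size and
    circularity constraints, peri-nuclear ring normalization,
    per-nucleus kinetic metrics (half-time of uptake, peri-normalized
    half-uptake level, maximum uptake rate from polynomial fits),
    cell-line-normalized cross-molecular-weight log-ratio tables with
    non-Fickian classification, control-normalized fold changes with
    propagated standard errors, factorial ANOVA / t-test / correlation
    stages, and a giant-unilamellar-vesicle dye-influx control analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    car,
    yaml,
    withr,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
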
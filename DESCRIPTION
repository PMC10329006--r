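Package: meiotrack
Title: Spindle-Frame Chromosome Dynamics in Oocyte Meiosis I
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying 4D chromosome dynamics in meiosis I
    oocytes from two-channel time-lapse stacks or point tracks. Includes a
    ground-truthed synthetic cohort simulator with genotype presets, spot
    detection and track linking, per-frame spindle reference-frame metrics
    (orientation angle, congression and axial-compaction distances,
    oscillation, bivalent stretching), control-cohort threshold calibration,
    per-timepoint state classification, anaphase segregation-fate and ploidy
    calling, angle-fate association statistics, and fluorescence-intensity
    quantification with background normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
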
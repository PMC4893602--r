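Package: beadRheo
Title: Passive Bead Rheology for High-Throughput Cell Compliance Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of passive particle-tracking
    microrheology experiments on multiwell plates: seeded generators for
    bead trajectories under elastic, Newtonian, confined and anomalous
    motion models, fluorescence video rendering and through-focus stacks,
    liquid-lens focus/scale calibration, sub-pixel spot detection and
    trajectory linking, audit-preserving motion-region video compression,
    mean-squared-displacement estimation with Bayesian model selection,
    AFM Hertzian force-curve analysis with automatic contact-point
    detection, and stratified rank statistics (van Elteren) for
    plate-blocked comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
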
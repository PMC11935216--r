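Package: barrierEIS
Title: Equivalent-Circuit Analysis of Barrier-Tissue Impedance Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of electrochemical impedance spectroscopy (EIS)
    recordings from 3D bioelectronic culture devices used to monitor
    epithelial gut-barrier integrity during host-microbe intervention
    experiments. Implements the forward equivalent-circuit model
    (R_CE//Q_CE)-R_electrolyte-(R_barrier//C_barrier) with a constant phase
    element, complex non-linear least-squares fitting with multistart global
    optimisation and a fixed series resistance, extraction of the barrier
    resistance R_b as the figure of merit for barrier integrity, normalised
    500 Hz impedance-magnitude cross-sections, 24-hour intervention
    time-course metrics (fold-changes versus baseline and versus controls),
    and the between-group statistics (Levene's test, one-way ANOVA, Tukey
    HSD) used to compare intervention arms. A seeded synthetic-data
    generator emulates the measurement protocol (100 kHz-100 mHz sweep at
    10 points per decade, replicated devices, programmed barrier-resistance
    trajectories) so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr,
    car
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
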
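Package: runsync
Title: Spontaneous Entrainment of Running Cadence to Music Tempo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying spontaneous
    entrainment of running cadence to music tempo. Provides a rated music
    stimulus library with tempo-based song selection, a four-lap
    cadence-adaptive tempo protocol with imperceptible tempo shifts, a
    circle-map (phase-error correction) runner simulator that generates
    step trains and synthetic tri-axial accelerometer traces, accelerometer
    step detection and cadence estimation, the cadence-adaptation and
    tempo-entrainment outcome measures, and the accompanying nonparametric
    statistical battery (Friedman, Wilcoxon signed-rank, Mann-Whitney,
    Spearman, Lilliefors-corrected Kolmogorov-Smirnov, repeated-measures
    ANOVA with polynomial trend contrast) including an entrainment-basin
    analysis against the zero-shift control condition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
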
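Package: circaphen
Title: Circadian Behavioral Phenotyping for Home-Cage Recordings Under
    Arbitrary Light Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for long-term home-cage phenotyping
    (locomotion, feeding, respiratory exchange ratio, energy expenditure)
    of mice housed under standard 12:12 or shortened T-cycle light
    schedules. Provides elastic zeitgeber-time conversion for non-24 h
    cycles, Gaussian-smoothed daily peak and onset detection, Rayleigh
    circular statistics on peak phases, the Sokolove-Bushell chi-square
    periodogram with significance thresholds and primary/secondary peak
    extraction, lagged cross-correlation between physiological channels,
    phase-binned and hourly zeitgeber-time summaries, fence-based quality
    control for hoarding artifacts and assay replicates, and a seeded
    simulator of entrained and environmentally desynchronized cohorts for
    testing every stage without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
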
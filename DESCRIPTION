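Package: ecogc
Title: Salinity, Migration and Genomic GC Content in Teleost Fishes
Version: 0.1.0
Authors@R:
    person("ecogc", "developers", email = "ecogc@example.org", role = c("aut", "cre"))
Description: Comparative analysis of teleost routine metabolic rate,
    specific gill area and average genomic GC content across salinity
    (freshwater/seawater) and lifestyle (migratory/non-migratory) groups.
    Provides ecological classification of species-trait tables, Boltzmann
    temperature normalization of metabolic rates, rank-based two-group
    tests with an exact small-sample path, two-way factorial ANOVA with a
    bootstrap assessment of main and interaction effects, a cross-variable
    convergence test for the top-ranked group, coding-sequence filtering
    with isochore GC binning and expression comparisons, seeded synthetic
    data generators, and a pipeline that orchestrates the full analysis
    into a reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
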
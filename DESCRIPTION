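Package: cageRT
Title: Simulation and Analysis of IntelliCage Reaction-Time Task Protocols
Version: 0.1.0
Authors@R:
    person("cageRT", "Maintainers", email = "maintainers@cagert.org", role = c("aut", "cre"))
Description: Tools for automated home-cage operant phenotyping with the
    IntelliCage apparatus. Implements a 34-day protocol calendar (adaptation,
    place preference and reversal, four progressively harder reaction-time
    tasks, place avoidance and extinction), a corner-contingency engine that
    adjudicates reaction-time trials into premature, correct and abandoned
    outcomes from raw visit/nose-poke/lick event streams, per-mouse per-day
    dependent-variable computation, a generative simulator of genotype-specific
    cohorts with closed-form outcome oracles, and a mixed repeated-measures
    ANOVA statistical layer with Bonferroni-corrected post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
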
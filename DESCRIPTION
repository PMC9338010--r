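Package: vissearch
Title: Simulation and Analysis of Eye-Movement Strategies in Oriented Line-Segment Visual Search
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers distribute fixations over search
    arrays of oriented line segments whose local distractor heterogeneity varies
    in space. Generates split-half arrays (one homogeneous and one heterogeneous
    half) and "jumbled" arrays whose per-cell orientation range is driven by a
    1/f^2 noise field histogram-equalised to a U-shaped parabolic reference
    distribution; simulates parametric observers that produce fixation
    sequences, target-present/absent responses and reaction times; classifies
    fixations as landing on heterogeneous or homogeneous regions and scores
    search strategy as the proportion of early target-absent fixations directed
    at heterogeneous regions; and provides group-level interval estimates,
    reaction-time correlation summaries and a parameter-recovery harness that
    validates the whole pipeline on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr,
    lme4,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
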
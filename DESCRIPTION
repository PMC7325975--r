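Package: rampulse
Title: Design, Simulation and Inference for Gradual Versus Abrupt Stressor
    Delivery Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dose-day-equalised stress-ecology experiments in which
    the same total stressor exposure is delivered either as a gradual ramp or
    as an abrupt step, modelled on liquid-culture copper-stress assays with
    filamentous soil fungi.  Builds and audits treatment schedules whose area
    under the concentration-time curve (dose-days) and final concentration
    match; simulates replicate-level biomass and metal-accumulation data from
    a mechanistic growth/uptake model with isolate-level heterogeneity;
    estimates per-isolate unstandardised effect sizes with percentile-bootstrap
    confidence intervals and a bootstrap gradual-vs-abrupt contrast; classifies
    isolates into reaction patterns and stress-response strategy quadrants;
    runs one-way ANOVA with Tukey HSD and Pearson correlations with Fisher-z
    intervals; and tests traits for phylogenetic signal with Blomberg's K and
    a tip-permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
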
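Package: pairspace
Title: Behavioral States, Contact-Call Rates, and Acoustic Active Space of
    Humpback Whale Female-Calf Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking the behavioral states of tagged humpback whale
    adult female-calf pairs to their vocal behavior and the acoustic active
    space of their contact calls. Movement metrics (speed, southerly speed,
    course deviation, energetic surface behaviors, surface proportion, and
    deep-dive frequency) are computed per 10-minute bin from position fixes
    and tag depth records, classified into resting/milling versus travelling
    states by k-means with a multi-index cluster-count vote, and related to
    per-state call rates (negative-binomial mixed models with a time offset),
    received call levels (linear mixed models), and call detection distances
    obtained by inverting a site-specific piecewise log-distance transmission
    loss model at a signal-to-noise ratio of zero. A seeded synthetic
    tag-data generator reproduces the statistical structure of such datasets
    for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    cluster,
    lme4,
    glmmTMB,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
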
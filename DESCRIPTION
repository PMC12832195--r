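Package: sealemerge
Title: Hidden Markov Models for Ringed Seal Emergence Timing from Haul-Out Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates when ringed seals switch from hauling out in snow lairs
    to basking openly on sea ice ("emergence") from satellite-tag wet/dry
    timelines. Converts hourly percent-dry records into daily proportion
    hauled out and circular peak haul-out hour, annotates them with
    environmental covariates (daylength, air temperature, thawing degree
    days, snow-melt indices, sea-ice concentration), and fits a constrained
    two-state hidden Markov model with zero-one-inflated beta and von Mises
    emissions, an absorbing emerged state, known February lair states, and
    logit-linear covariate effects on the daily emergence probability.
    Includes Viterbi decoding of per-seal emergence dates, leave-one-out
    sensitivity analysis, AIC model selection over a fixed candidate set,
    post-hoc spatiotemporal trend regressions, and a synthetic-data
    generator for the full observation process.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
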
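# sealemerge

Ringed seals (*Pusa hispida*) overwinter in snow lairs excavated over
breathing holes in sea ice and, as spring advances, abandon them to bask
openly on the ice while molting — a one-directional behavioral switch
called **emergence**. Emergence timing matters for interpreting aerial
population surveys (only basking seals are countable) and for anticipating
how earlier Arctic melt affects a lair-dependent species. Satellite tags
record hourly wet/dry data but cannot see whether a dry seal is concealed
in a lair; `sealemerge` infers emergence from the *pattern* of haul-out
behavior instead.

The package is for quantitative ecologists working with wet/dry telemetry
from ice seals: it converts hourly percent-dry timelines into daily
behavioral observations, fits a constrained hidden Markov model, decodes
per-seal emergence dates, and analyzes spatiotemporal trends in them.

## The model

Each seal-year is a daily time series of two observed variables:

* **proportion of the day hauled out** `prop_t ∈ [0, 1]`, modeled with a
  zero–one-inflated beta: point masses `π0`, `π1` at 0 and 1 and a
  Beta(a, b) density between;
* **peak haul-out hour** `θ_t ∈ [−π, π)` (weighted circular mean of the
  day's haul-out, solar noon = 0), modeled with a von Mises(μ, κ).

A hidden two-state chain drives both: a **lair** state (little time
hauled out, diffuse nocturnal peak) and an **emerged** state (much more
time hauled out, concentrated diurnal peak). Three constraints encode the
biology:

1. emerged is absorbing — `P(emerged → emerged) = 1`;
2. every February day is known to be lair;
3. the daily emergence probability is logit-linear in covariates,
   `logit p_t = β′x_t` (day of year, daylength, air temperature, melt
   indices, sea-ice concentration, …), chosen from a fixed 15-model
   candidate set by AIC.

Every admissible state path is therefore monotone, and the Viterbi-decoded
switch day is the seal's emergence date. Parameters (8 inflated-beta + 4
von Mises + 1 initial-state + the transition coefficients, i.e. 14–17
total depending on the formula) are estimated by maximum likelihood with
the scaled forward algorithm.

## Worked example

A complete synthetic study — simulate tagged seals from the generative
model, fit the HMM, decode emergence dates:

```r
library(sealemerge)

cfg <- sim_config(n_seals = 8, seed = 7)   # Feb–Jun season, adult-like truth
sim <- simulate_emergence_study(cfg)

fit <- emergence_hmm(~ air_temp + daylength, sim$daily_series,
                     nstarts = 2, seed = 3)
summary(fit)
#> State-dependent distributions:
#>     state       p0     p1 shape1 shape2 mean_prop sd_prop     mu kappa peak_solar_hour
#> 1    lair 3.52e-01 0.0037   1.25   2.97     0.194   0.219 -3.039 0.443           0.392
#> 2 emerged 1.41e-06 0.0299   1.86   1.67     0.541   0.245 -0.059 5.460          11.774
#>
#> Transition coefficients (natural covariate scale):
#>          term estimate     se      z  p_value
#> 1 (Intercept) -28.2615 9.9010 -2.854 0.004312
#> 2    air_temp   0.4277 0.1935  2.210 0.027077
#> 3   daylength   1.2241 0.4534  2.700 0.006943
#> logLik -1498.19  k = 16  AIC 3028.38  converged: TRUE

decoded <- viterbi(fit)
emergence_dates(decoded, sim$daily_series)[, 1:3]
#>   seal_year_id emergence_date emergence_doy
#> 1  seal01_2015     2015-05-19           139
#> 2  seal02_2015     2015-05-21           141
#> ...
```

The fitted states recover the generating behavior: the lair state hauled
out ~19% of the day with a diffuse nocturnal peak, the emerged state ~54%
with a sharp peak just before solar noon, and positive temperature and
daylength effects on the daily emergence probability. Seven of the eight
decoded emergence dates equal the simulated truth exactly.

Downstream, `state_summaries()` gives per-state behavior tables,
`select_models()` ranks the candidate covariate set by AIC,
`leave_one_out()` measures the sensitivity of each seal's emergence date
to the rest of the sample, and `fit_trend()` / `predict_mean()` regress
emergence day-of-year on latitude or year with AICc comparison.

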
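# wrap a parameter set into a minimal fitted-model shell for viterbi()
as_fit <- function(params, data) {
  structure(list(params = params, data = data, convergence = TRUE),
            class = "emergence_hmm")
}

test_that("Viterbi path equals exhaustive monotone-path enumeration", {
  set.seed(201)
  n_checked <- 0
  for (i in 1:200) {
    d <- random_series()
    pars <- random_params("x")
    dec <- viterbi(as_fit(pars, d))
    oracle <- oracle_viterbi(pars, d)
    expect_identical(dec$state, oracle)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("series entirely in February decodes to all lair", {
  d <- data.frame(seal_year_id = "s1",
                  date = seq(as.Date("2015-02-01"), by = "day", length.out = 20),
                  prop_ho = runif(20, 0.4, 0.9), peak_hr = rnorm(20, 0, 0.2),
                  x = rnorm(20))
  pars <- random_params("x")
  expect_true(all(viterbi(as_fit(pars, d))$state == "lair"))
})

test_that("zero emergence probability forces an all-lair path", {
  sim <- simulate_emergence_study(sim_config(n_seals = 3, seed = 71))
  pars <- adult_like_params()
  pars$beta[] <- 0
  pars$beta["(Intercept)"] <- -800 # underflows to an exact zero probability
  pars$delta <- 0
  dec <- viterbi(as_fit(pars, sim$daily_series))
  expect_true(all(dec$state == "lair"))
  ed <- emergence_dates(dec)
  expect_equal(nrow(ed), 0)
  expect_equal(nrow(attr(ed, "not_emerged")), 3)
})

test_that("decoded path beats random monotonicity-respecting perturbations", {
  set.seed(202)
  pars <- adult_like_params()
  sim <- simulate_emergence_study(sim_config(n_seals = 2, seed = 72))
  d <- sim$daily_series
  d1 <- d[d$seal_year_id == d$seal_year_id[1], ]
  dec <- viterbi(as_fit(pars, d1))
  path_logp <- function(states) {
    tau <- if (any(states == "emerged")) min(which(states == "emerged")) else nrow(d1) + 1
    feb <- format(d1$date, "%m") == "02"
    e <- oracle_emissions(pars, d1$prop_ho, d1$peak_hr, feb)
    eta <- pars$beta[["(Intercept)"]] + pars$beta[["air_temp"]] * d1$air_temp +
      pars$beta[["daylength"]] * d1$daylength
    log(oracle_path_prob(tau, pars, e, plogis(eta)))
  }
  best <- path_logp(dec$state)
  for (shift in c(-5, -1, 1, 5, 20)) {
    tau0 <- if (any(dec$state == "emerged")) min(which(dec$state == "emerged")) else nrow(d1) + 1
    tau <- min(max(tau0 + shift, 1), nrow(d1) + 1)
    states <- rep("lair", nrow(d1))
    if (tau <= nrow(d1)) states[tau:nrow(d1)] <- "emerged"
    expect_lte(path_logp(states), best + 1e-10)
  }
})

test_that("emergence dates and coverage diagnostics are extracted correctly", {
  dates <- seq(as.Date("2015-03-01"), by = "day", length.out = 80)
  dec <- rbind(
    data.frame(seal_year_id = "a", date = dates,
               state = c(rep("lair", 50), rep("emerged", 30))),
    data.frame(seal_year_id = "b", date = dates, state = "lair"))
  ed <- emergence_dates(dec)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$emergence_date, dates[51])
  expect_equal(ed$emergence_doy, as.integer(format(dates[51], "%j")))
  ne <- attr(ed, "not_emerged")
  expect_equal(ne$seal_year_id, "b")
  expect_equal(ne$first_date, dates[1])
})

test_that("state summaries compute per-state arithmetic and circular means", {
  dates <- seq(as.Date("2015-03-01"), by = "day", length.out = 4)
  series <- data.frame(seal_year_id = "a", date = dates,
                       prop_ho = c(0.1, 0.2, 0.5, 0.7),
                       peak_hr = c(-0.1, 0.1, -0.1, 0.1))
  dec <- data.frame(seal_year_id = "a", date = dates,
                    state = c("lair", "lair", "emerged", "emerged"))
  ss <- state_summaries(dec, series)
  expect_equal(ss$mean_prop_pct, c(15, 60))
  expect_equal(ss$peak_mean_rad, c(0, 0))
  expect_equal(ss$peak_solar_hour, c(12, 12))
  # one-state-only data flags the other state as empty
  dec2 <- dec; dec2$state <- "lair"
  ss2 <- state_summaries(dec2, series)
  expect_equal(ss2$n_prop[ss2$state == "emerged"], 0)
  expect_true(is.na(ss2$mean_prop_pct[ss2$state == "emerged"]))
})

test_that("state summaries converge to the generating emission means", {
  cfg <- sim_config(n_seals = 40, start = as.Date("2015-03-01"),
                    end = as.Date("2015-07-18"), seed = 73,
                    missingness = list(p_gap_start = 0, gap_mean = 1))
  sim <- simulate_emergence_study(cfg)
  truth <- sim$true_states
  ss <- state_summaries(
    data.frame(seal_year_id = truth$seal_year_id, date = truth$date,
               state = truth$true_state),
    sim$daily_series)
  pars <- adult_like_params()
  for (s in c("lair", "emerged")) {
    mo <- zoib_moments(pars[[s]]$p0, pars[[s]]$p1,
                       pars[[s]]$shape1, pars[[s]]$shape2)
    got <- ss$mean_prop_pct[ss$state == s] / 100
    expect_equal(got, unname(mo["mean"]), tolerance = 0.03)
  }
})

test_that("leave-one-out refits each unit once and identical seals give SD 0", {
  cfg <- sim_config(n_seals = 6, seed = 81,
                    missingness = list(p_gap_start = 0, gap_mean = 1))
  sim <- simulate_emergence_study(cfg)
  fit <- emergence_hmm(~ air_temp + daylength, sim$daily_series,
                       nstarts = 1, seed = 2)
  loo <- leave_one_out(fit, nstarts = 1)
  expect_equal(nrow(loo), 6)
  dates <- attr(loo, "dates")
  expect_equal(ncol(dates), 6) # one refit per held-out seal
  # each seal appears in all iterations except its own
  expect_true(all(loo$n_iterations <= 5))
  # emergence dating is highly stable across iterations on clean data
  expect_true(all(loo$sd_days[loo$n_iterations > 1] <= 1.5, na.rm = TRUE))
})
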
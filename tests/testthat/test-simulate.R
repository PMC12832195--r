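test_that("simulated covariates follow the seasonal ramp and are reproducible", {
  cfg <- sim_config(n_seals = 3, seed = 42)
  a <- simulate_covariates(cfg)
  b <- simulate_covariates(cfg)
  expect_identical(a, b) # fixed seed -> byte-identical
  # zero-noise ramp hits the winter asymptote far below the midpoint
  cfg0 <- sim_config(n_seals = 1, start = as.Date("2015-02-01"),
                     end = as.Date("2015-03-01"),
                     temp_model = list(winter_mean = -25, spring_mean = 5,
                                       ramp_midpoint = 130, ramp_width = 10,
                                       daily_noise_sd = 0),
                     seed = 1)
  t0 <- simulate_covariates(cfg0)
  expect_equal(t0$air_temp, rep(-25, nrow(t0)), tolerance = 0.02)
  expect_error(sim_config(n_seals = 1, start = as.Date("2015-05-01"),
                          end = as.Date("2015-05-01")))
})

test_that("temperature at the ramp midpoint averages the two asymptotes", {
  cfg <- sim_config(n_seals = 1000, start = as.Date("2015-05-08"),
                    end = as.Date("2015-05-12"),
                    temp_model = list(winter_mean = -25, spring_mean = 5,
                                      ramp_midpoint = 130, ramp_width = 10,
                                      daily_noise_sd = 2),
                    seed = 99)
  cov <- simulate_covariates(cfg)
  at_mid <- cov$air_temp[cov$doy == 130]
  # analytic mean of the logistic ramp at its midpoint is (-25 + 5)/2
  expect_equal(mean(at_mid), -10, tolerance = 4 * 2 / sqrt(1000))
})

test_that("latent paths are monotone with a geometric waiting time under constant hazard", {
  cfg <- sim_config(n_seals = 3000, start = as.Date("2015-03-01"),
                    end = as.Date("2015-05-29"), seed = 2)
  cov <- simulate_covariates(cfg)
  pars <- adult_like_params()
  pars$beta <- c("(Intercept)" = qlogis(0.1))
  pars$delta <- 0
  st <- simulate_states(cov, pars, seed = 3)
  # monotone: never emerged -> lair
  for (id in unique(st$seal_year_id)[1:50]) {
    s <- st$true_state[st$seal_year_id == id]
    expect_true(all(diff(s == "emerged") >= 0))
  }
  # waiting time from the series start is geometric(0.1): mean 10 days
  first <- tapply(st$true_state == "emerged", st$seal_year_id, function(z) {
    i <- which(z); if (length(i)) i[1] else NA_integer_
  })
  waits <- first[!is.na(first)] - 1 # transitions start on day 2
  expect_equal(mean(waits), 10, tolerance = 0.6)
})

test_that("degenerate transition intercepts pin the latent paths", {
  cfg <- sim_config(n_seals = 30, start = as.Date("2015-03-01"),
                    end = as.Date("2015-03-20"), seed = 4)
  cov <- simulate_covariates(cfg)
  pars <- adult_like_params(); pars$delta <- 0
  pars$beta <- c("(Intercept)" = -50)
  expect_true(all(simulate_states(cov, pars, 5)$true_state == "lair"))
  pars$beta <- c("(Intercept)" = 50)
  st <- simulate_states(cov, pars, 5)
  for (id in unique(st$seal_year_id)) {
    s <- st$true_state[st$seal_year_id == id]
    expect_equal(s[1], "lair")
    expect_true(all(s[-1] == "emerged")) # constant p = 1 -> emerge on day 2
  }
})

test_that("observations follow the state emission model", {
  cfg <- sim_config(n_seals = 40, start = as.Date("2015-03-01"),
                    end = as.Date("2015-04-19"), seed = 6)
  cov <- simulate_covariates(cfg)
  pars <- adult_like_params()
  # lair mass at zero = 1: every lair day has prop 0 and a missing peak hour
  pars1 <- pars
  pars1$lair[c("p0", "p1")] <- list(1, 0)
  st <- simulate_states(cov, pars1, 7)
  obs <- simulate_observations(st, pars1,
                               missingness = list(p_gap_start = 0, gap_mean = 1),
                               seed = 8)
  lair <- obs$true_state == "lair"
  expect_true(all(obs$prop_ho[lair] == 0))
  expect_true(all(is.na(obs$peak_hr[lair])))
  # highly concentrated emerged peak hours recover the mean direction
  pars2 <- pars
  pars2$emerged[c("mu", "kappa", "p0", "p1")] <- list(0, 50, 0, 0)
  pars2$beta <- c("(Intercept)" = 2) # emerge fast for plenty of emerged days
  st2 <- simulate_states(cov, pars2, 9)
  obs2 <- simulate_observations(st2, pars2,
                                missingness = list(p_gap_start = 0, gap_mean = 1),
                                seed = 10)
  pk <- obs2$peak_hr[obs2$true_state == "emerged"]
  pk <- pk[!is.na(pk)]
  expect_gt(length(pk), 1000)
  expect_lt(abs(circular_mean(pk)), 0.05)
  # no-gap runs have missing observations only via the 0/1 rule
  expect_true(all(!is.na(obs2$prop_ho)))
  expect_true(all(is.na(obs2$peak_hr) == (obs2$prop_ho %in% c(0, 1))))
})

test_that("transmission gaps blank whole days in contiguous blocks", {
  cfg <- sim_config(n_seals = 10, seed = 12,
                    missingness = list(p_gap_start = 0.05, gap_mean = 5))
  sim <- simulate_emergence_study(cfg)
  d <- sim$daily_series
  gap_days <- is.na(d$prop_ho)
  expect_gt(mean(gap_days), 0.02)
  expect_true(all(is.na(d$peak_hr[gap_days])))
})

test_that("truth tables are internally consistent and reproducible", {
  cfg <- sim_config(n_seals = 6, seed = 13)
  s1 <- simulate_emergence_study(cfg)
  s2 <- simulate_emergence_study(cfg)
  expect_identical(s1$daily_series, s2$daily_series)
  expect_identical(s1$true_emergence_dates, s2$true_emergence_dates)
  # emergence date equals the first emerged day
  for (k in seq_len(nrow(s1$true_emergence_dates))) {
    id <- s1$true_emergence_dates$seal_year_id[k]
    ed <- s1$true_emergence_dates$emergence_date[k]
    ts <- s1$true_states[s1$true_states$seal_year_id == id, ]
    if (is.na(ed)) {
      expect_true(all(ts$true_state == "lair"))
    } else {
      expect_equal(min(ts$date[ts$true_state == "emerged"]), ed)
      expect_true(all(ts$true_state[ts$date >= ed] == "emerged"))
    }
  }
})
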
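test_that("parameter counts reproduce the candidate-set structure", {
  d <- data.frame(doy = 1:6, sex = factor(rep(c("F", "M"), 3)),
                  latitude = 70, year = 2015, daylength = 12, sic = 0.9,
                  air_temp = -5, temp_7day = -5, tdd = 0,
                  melt_early_index = -10, melt_cont_index = -12)
  expect_equal(count_parameters(~ air_temp + daylength, d), 16)
  expect_equal(count_parameters(~ doy * sex, d), 17)
  expect_equal(count_parameters(~ 1, d), 14)
  ks <- vapply(candidate_formulas(), count_parameters, integer(1), data = d)
  expect_length(ks, 15)
  expect_true(all(ks >= 14 & ks <= 17))
  # count identity: 13 emission/initial parameters + transition columns
  for (f in candidate_formulas()) {
    expect_equal(count_parameters(f, d), 13 + ncol(model.matrix(f, d)))
  }
})

test_that("forward log-likelihood equals monotone-path enumeration for short series", {
  set.seed(101)
  for (i in 1:200) {
    d <- random_series()
    pars <- random_params("x")
    ll_fwd <- hmm_loglik(pars, d)
    ll_enum <- oracle_loglik(pars, d)
    if (is.finite(ll_enum)) {
      expect_equal(ll_fwd, ll_enum, tolerance = 1e-8)
    } else {
      expect_true(!is.finite(ll_fwd))
    }
  }
})

test_that("a single all-missing day with a forced lair start has log-likelihood 0", {
  d <- data.frame(seal_year_id = "s1", date = as.Date("2015-03-01"),
                  prop_ho = NA_real_, peak_hr = NA_real_)
  pars <- adult_like_params()
  pars$beta <- c("(Intercept)" = 0)
  pars$delta <- 0
  expect_equal(hmm_loglik(pars, d), 0)
})

test_that("February known-state constraint equals forcing the lair emission", {
  # an emerged-looking February observation still contributes the lair term
  set.seed(102)
  d <- data.frame(seal_year_id = "s1",
                  date = seq(as.Date("2015-02-20"), by = "day", length.out = 6),
                  prop_ho = c(0.9, 0.85, 0.8, 0.9, 0.2, 0.1),
                  peak_hr = c(0, 0.1, -0.1, 0, 2.8, 3),
                  x = rnorm(6))
  pars <- random_params("x")
  ll <- hmm_loglik(pars, d)
  # hand construction: February days (1-4 here + March tail free) restricted
  hand <- 0
  feb <- format(d$date, "%m") == "02"
  e <- oracle_emissions(pars, d$prop_ho, d$peak_hr, feb)
  p <- plogis(pars$beta[["(Intercept)"]] + pars$beta[["x"]] * d$x)
  w <- vapply(seq_len(nrow(d) + 1), oracle_path_prob, numeric(1),
              params = pars, e = e, p = p)
  # paths transitioning during February have zero weight
  expect_true(all(w[seq_len(sum(feb))] == 0))
  expect_equal(ll, log(sum(w)), tolerance = 1e-10)
})

test_that("transition matrix rows are stochastic with an absorbing emerged row", {
  beta <- c("(Intercept)" = 0.3, air_temp = 0.2)
  tm <- transition_matrix(data.frame(air_temp = -1.5), beta)
  expect_equal(rowSums(tm), c(lair = 1, emerged = 1))
  expect_equal(tm["emerged", ], c(lair = 0, emerged = 1))
  expect_equal(tm["lair", "emerged"], plogis(0.3 - 0.3), ignore_attr = TRUE)
  # logistic(0) = 0.5 at a zero linear predictor
  expect_equal(unname(transition_matrix(data.frame(air_temp = 0),
                                        c("(Intercept)" = 0, air_temp = 1))["lair", "emerged"]),
               0.5)
  # monotone in a positive-coefficient covariate
  ps <- vapply(c(-10, -5, 0, 5), function(tmp)
    transition_matrix(data.frame(air_temp = tmp), beta)["lair", "emerged"],
    numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_error(transition_matrix(data.frame(air_temp = NA_real_), beta), "missing")
})

test_that("fitting improves on the starting values and is deterministic", {
  sim <- simulate_emergence_study(sim_config(n_seals = 6, seed = 21))
  d <- sim$daily_series
  inits <- sealemerge:::.default_inits(c("(Intercept)", "air_temp"))
  fit1 <- emergence_hmm(~ air_temp, d, inits = inits, nstarts = 2, seed = 5)
  fit2 <- emergence_hmm(~ air_temp, d, inits = inits, nstarts = 2, seed = 5)
  expect_true(fit1$convergence)
  expect_gte(fit1$logLik, hmm_loglik(inits, d))
  expect_identical(fit1$working, fit2$working)
  # AIC identity
  expect_equal(fit1$AIC, -2 * fit1$logLik + 2 * fit1$npar)
  expect_equal(fit1$npar, count_parameters(~ air_temp, d))
})

test_that("likelihood ignores covariates on emission-missing days only via transitions", {
  # changing a covariate on a day with missing observations still changes the
  # likelihood (the transition term uses it), while changing the observation
  # channel handling does not
  sim <- simulate_emergence_study(sim_config(n_seals = 3, seed = 31))
  d <- sim$daily_series
  pars <- adult_like_params()
  i <- which(is.na(d$prop_ho))[1]
  skip_if(is.na(i))
  d2 <- d; d2$air_temp[i] <- d2$air_temp[i] + 15
  expect_false(isTRUE(all.equal(hmm_loglik(pars, d), hmm_loglik(pars, d2))))
})

test_that("model selection ranks by AIC with the best at delta 0", {
  sim <- simulate_emergence_study(sim_config(n_seals = 8, seed = 41))
  d <- annotate_series(sim$daily_series)
  tab <- select_models(d, formulas = list(none = ~ 1, air_temp = ~ air_temp,
                                          daylength = ~ daylength),
                       nstarts = 1, seed = 2)
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$AIC) >= 0))
  expect_true(tab$best[1])
  expect_equal(tab$k[tab$model == "none"], 14)
})

test_that("emergence curve is 0.5 at a zero predictor with a symmetric logit CI", {
  sim <- simulate_emergence_study(sim_config(n_seals = 8, seed = 51))
  d <- sim$daily_series
  fit <- emergence_hmm(~ air_temp, d, nstarts = 1, seed = 2)
  nd <- data.frame(air_temp = seq(-30, 10, by = 5))
  pr <- predict(fit, nd)
  expect_true(all(pr$lower <= pr$p & pr$p <= pr$upper))
  expect_true(all(diff(pr$p) >= 0)) # positive temperature effect
  # point where the standardized predictor crosses zero has p = plogis(b0)
  ctr <- fit$standardization$center[2]
  pr0 <- predict(fit, data.frame(air_temp = ctr))
  expect_equal(pr0$p, plogis(fit$beta_std[["(Intercept)"]]))
  # CI is symmetric on the logit scale around the estimate
  expect_equal(qlogis(pr0$p) - qlogis(pr0$lower), qlogis(pr0$upper) - qlogis(pr0$p),
               tolerance = 1e-8)
  # extrapolation flagged outside the observed range
  prx <- predict(fit, data.frame(air_temp = 100))
  expect_true(prx$extrapolated)
})

test_that("delta-method CI matches a parametric bootstrap on a synthetic fit", {
  set.seed(61)
  sim <- simulate_emergence_study(sim_config(n_seals = 10, seed = 61))
  d <- sim$daily_series
  fit <- emergence_hmm(~ air_temp, d, nstarts = 1, seed = 2)
  bi <- (sealemerge:::.n_fixed + 1):length(fit$working)
  V <- fit$vcov_working[bi, bi]
  draws <- MASS::mvrnorm(10000, fit$beta_std, V)
  nd <- data.frame(air_temp = c(-8, -4, 0))
  pr <- predict(fit, nd)
  st <- fit$standardization
  for (k in seq_len(nrow(nd))) {
    xs <- c(1, (nd$air_temp[k] - st$center[2]) / st$scale[2])
    sim_p <- plogis(draws %*% xs)
    expect_lt(abs(quantile(sim_p, 0.025) - pr$lower[k]), 0.02)
    expect_lt(abs(quantile(sim_p, 0.975) - pr$upper[k]), 0.02)
  }
})
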
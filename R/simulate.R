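#' Parameter set for the two-state emergence HMM
#'
#' Container for the natural-scale parameters of the constrained two-state
#' model: per-state zero-one-inflated beta (`p0`, `p1`, `shape1`, `shape2`)
#' and von Mises (`mu`, `kappa`) emission parameters, logit-linear
#' transition coefficients `beta` (named vector; names are covariate
#' columns plus `"(Intercept)"`) on the daily lair-to-emerged probability,
#' and `delta`, the probability of starting the series already emerged.
#'
#' @param lair,emerged lists with elements `p0`, `p1`, `shape1`, `shape2`,
#'   `mu`, `kappa`.
#' @param beta named numeric vector of transition coefficients on the
#'   natural covariate scale; must include `"(Intercept)"`.
#' @param delta probability in \[0, 1\] that a seal is already emerged on
#'   its first observed day.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(lair, emerged, beta, delta = 0.02) {
  for (s in list(lair, emerged)) {
    stopifnot(s$p0 >= 0, s$p1 >= 0, s$p0 + s$p1 <= 1,
              s$shape1 > 0, s$shape2 > 0, s$kappa >= 0)
  }
  stopifnot("(Intercept)" %in% names(beta), delta >= 0, delta <= 1)
  structure(list(lair = lair, emerged = emerged,
                 beta = beta, delta = delta),
            class = "hmm_params")
}

#' Adult-like generating parameters
#'
#' Default truth for the synthetic study, chosen to mirror the behavior of
#' adult ringed seals: a lair state hauled out ~19% of the day on average
#' (mass at zero ~0.35, i.e. many days entirely in the water) with a
#' diffuse, nocturnal peak hour (mean +2.83 rad ~ 22:48 solar,
#' concentration 0.5); an emerged state hauled out ~55% of the day with a
#' sharply diurnal peak hour (mean -0.05 rad ~ 11:48 solar, concentration
#' 5); and positive air-temperature and daylength effects on the daily
#' emergence probability, placing most transitions in mid-to-late May.
#'
#' @return an [hmm_params()] object.
#' @export
adult_like_params <- function() {
  hmm_params(
    lair    = list(p0 = 0.35, p1 = 0.005, shape1 = 1.2, shape2 = 2.98,
                   mu = 2.83, kappa = 0.5),
    emerged = list(p0 = 0.005, p1 = 0.03, shape1 = 2.0, shape2 = 1.71,
                   mu = -0.05, kappa = 5),
    beta = c("(Intercept)" = -14, air_temp = 0.25, daylength = 0.55),
    delta = 0.02
  )
}

#' Configuration for the synthetic emergence study
#'
#' @param n_seals number of simulated seal-years (>= 1).
#' @param start,end `Date` range of each record (the tag season).
#' @param latitude_range numeric length-2, degrees N within \[50, 85\].
#' @param true_params generating [hmm_params()].
#' @param temp_model list: `winter_mean` and `spring_mean` (deg C),
#'   `ramp_midpoint` (DOY), `ramp_width` (days), `daily_noise_sd` (deg C).
#'   Air temperature follows a logistic seasonal ramp between the two
#'   asymptotes plus iid Gaussian daily noise.
#' @param missingness list: `p_gap_start` (per-day probability a
#'   transmission gap begins) and `gap_mean` (mean gap length, days;
#'   geometric lengths).
#' @param seed master integer seed; all per-seal substreams derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_seals = 40,
                       start = as.Date("2015-02-01"),
                       end = as.Date("2015-06-30"),
                       latitude_range = c(66, 72),
                       true_params = adult_like_params(),
                       temp_model = list(winter_mean = -25, spring_mean = 5,
                                         ramp_midpoint = 130, ramp_width = 10,
                                         daily_noise_sd = 2),
                       missingness = list(p_gap_start = 0.03, gap_mean = 4),
                       seed = 1L) {
  stopifnot(n_seals >= 1, start < end,
            latitude_range[1] >= 50, latitude_range[2] <= 85,
            inherits(true_params, "hmm_params"))
  if (as.numeric(end - start) < 1) stop("date range must span at least 2 days")
  structure(list(n_seals = n_seals, start = start, end = end,
                 latitude_range = latitude_range, true_params = true_params,
                 temp_model = temp_model, missingness = missingness,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-seal covariate trajectories
#'
#' One stationary location per seal-year (latitude uniform over the
#' configured range; ringed seals occupy small home ranges before
#' breakup), a daily air-temperature series following the configured
#' logistic seasonal ramp plus independent Gaussian noise, and
#' deterministic daylength from DOY and latitude.
#'
#' @param config a [sim_config()].
#' @return data.frame: `seal_year_id`, `date`, `doy`, `year`, `latitude`,
#'   `longitude`, `air_temp`, `daylength`, `sex`, `age_class`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (as.numeric(config$end - config$start) < 1) {
    stop("date range must span at least 2 days")
  }
  set.seed(config$seed)
  n <- config$n_seals
  lat <- stats::runif(n, config$latitude_range[1], config$latitude_range[2])
  lon <- stats::runif(n, -170, -140)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  dates <- seq(config$start, config$end, by = "day")
  tm <- config$temp_model
  doy <- as.integer(format(dates, "%j"))
  ramp <- tm$winter_mean + (tm$spring_mean - tm$winter_mean) *
    stats::plogis((doy - tm$ramp_midpoint) / tm$ramp_width)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    temp <- ramp + stats::rnorm(length(dates), 0, tm$daily_noise_sd)
    out[[i]] <- data.frame(
      seal_year_id = sprintf("seal%02d_%s", i, format(config$start, "%Y")),
      date = dates, doy = doy,
      year = as.integer(format(dates, "%Y")),
      latitude = lat[i], longitude = lon[i],
      air_temp = temp,
      daylength = daylength(doy, lat[i]),
      sex = sex[i], age_class = "adult",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# daily emergence probability on a covariate table, natural-scale beta
.emergence_prob <- function(covariates, beta) {
  terms <- setdiff(names(beta), "(Intercept)")
  miss <- setdiff(terms, names(covariates))
  if (length(miss)) stop("covariate column(s) missing: ", paste(miss, collapse = ", "))
  eta <- rep(beta[["(Intercept)"]], nrow(covariates))
  for (tm in terms) eta <- eta + beta[[tm]] * covariates[[tm]]
  stats::plogis(eta)
}

#' Simulate latent state sequences
#'
#' Day 1 is emerged with probability `delta`, else lair; thereafter each
#' lair day transitions to emerged with the logit-linear daily probability
#' evaluated at that day's covariates. Emerged is absorbing, so every
#' simulated path is monotone (lair ... lair, emerged ... emerged).
#'
#' @param covariates covariate table from [simulate_covariates()] (must be
#'   complete: no missing rows).
#' @param true_params an [hmm_params()].
#' @param seed integer seed.
#' @return `covariates` with a `true_state` column (`"lair"`/`"emerged"`).
#' @export
simulate_states <- function(covariates, true_params, seed = 1L) {
  stopifnot(inherits(true_params, "hmm_params"))
  set.seed(seed)
  p <- .emergence_prob(covariates, true_params$beta)
  covariates$true_state <- NA_character_
  for (id in unique(covariates$seal_year_id)) {
    i <- which(covariates$seal_year_id == id)
    st <- character(length(i))
    st[1] <- if (stats::runif(1) < true_params$delta) "emerged" else "lair"
    for (k in seq_along(i)[-1]) {
      st[k] <- if (st[k - 1] == "emerged") "emerged"
               else if (stats::runif(1) < p[i[k]]) "emerged" else "lair"
    }
    covariates$true_state[i] <- st
  }
  covariates
}

#' Simulate daily haul-out observations
#'
#' Draws each day's proportion hauled out from the state's zero-one
#' -inflated beta and its peak haul-out hour from the state's von Mises;
#' the peak hour is set missing whenever the drawn proportion is exactly 0
#' or 1 (no diel information). A transmission-gap process then blanks both
#' observations over contiguous runs of days: each day starts a gap with
#' probability `p_gap_start`, with geometric gap lengths of the configured
#' mean.
#'
#' @param states table from [simulate_states()] (monotone `true_state`).
#' @param true_params an [hmm_params()].
#' @param missingness list with `p_gap_start`, `gap_mean`; use
#'   `p_gap_start = 0` for complete records.
#' @param seed integer seed.
#' @return `states` with `prop_ho` and `peak_hr` columns.
#' @export
simulate_observations <- function(states, true_params,
                                  missingness = list(p_gap_start = 0.03, gap_mean = 4),
                                  seed = 1L) {
  stopifnot(inherits(true_params, "hmm_params"), "true_state" %in% names(states))
  set.seed(seed)
  n <- nrow(states)
  prop <- peak <- rep(NA_real_, n)
  for (s in c("lair", "emerged")) {
    i <- which(states$true_state == s)
    if (!length(i)) next
    sp <- true_params[[s]]
    prop[i] <- rzoib(length(i), sp$p0, sp$p1, sp$shape1, sp$shape2)
    peak[i] <- rvonmises(length(i), sp$mu, sp$kappa)
  }
  peak[prop %in% c(0, 1)] <- NA_real_
  states$prop_ho <- prop
  states$peak_hr <- peak
  if (missingness$p_gap_start > 0) {
    for (id in unique(states$seal_year_id)) {
      i <- which(states$seal_year_id == id)
      gap <- rep(FALSE, length(i))
      k <- 1L
      while (k <= length(i)) {
        if (stats::runif(1) < missingness$p_gap_start) {
          len <- 1L + stats::rgeom(1, 1 / missingness$gap_mean)
          gap[k:min(length(i), k + len - 1L)] <- TRUE
          k <- k + len
        } else {
          k <- k + 1L
        }
      }
      states$prop_ho[i][gap] <- NA_real_
      states$peak_hr[i][gap] <- NA_real_
    }
  }
  states
}

#' Render daily observations back into hourly percent-dry timelines
#'
#' Inverse of the daily summarization, for end-to-end tests of the
#' preprocessing stage. Each observed day's haul-out time is packed into a
#' contiguous block of hours centered on the peak haul-out hour (full
#' hours at 100%, one remainder hour with the leftover percent), so that
#' re-running the preprocessing recovers the daily proportion within 1/24
#' and the peak hour within one hour-bin. Days with missing observations
#' produce no hourly rows (a transmission gap).
#'
#' @param daily_series table with `seal_year_id`, `date`, `prop_ho`,
#'   `peak_hr`, `longitude`.
#' @param seed unused (the allocation is deterministic); kept for interface
#'   stability.
#' @return data.frame: `seal_year_id`, `timestamp` (UTC, hourly),
#'   `percent_dry`.
#' @export
render_hourly <- function(daily_series, seed = 1L) {
  rows <- vector("list", nrow(daily_series))
  for (k in seq_len(nrow(daily_series))) {
    d <- daily_series[k, ]
    if (is.na(d$prop_ho)) next
    pct <- numeric(24)
    if (d$prop_ho >= 1) {
      pct[] <- 100
    } else if (d$prop_ho > 0) {
      total <- d$prop_ho * 2400
      center <- if (is.na(d$peak_hr)) 0 else d$peak_hr
      sh_mid <- solar_hour(0:23 + 0.5, d$longitude)
      dist <- abs(wrap_angle(solar_hour_to_radians(sh_mid) - center))
      ord <- order(dist)
      full <- floor(total / 100)
      if (full > 0) pct[ord[seq_len(full)]] <- 100
      rem <- total - full * 100
      if (rem > 1e-9) pct[ord[full + 1L]] <- rem
    }
    rows[[k]] <- data.frame(
      seal_year_id = d$seal_year_id,
      timestamp = as.POSIXct(paste(d$date, "00:00:00"), tz = "UTC") + 3600 * (0:23),
      percent_dry = pct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic emergence study
#'
#' Runs the full generative model: covariate trajectories, monotone latent
#' state paths, daily observations with transmission gaps, and the truth
#' tables downstream stages are validated against.
#'
#' @param config a [sim_config()].
#' @return list with `daily_series` (observations + covariates),
#'   `true_states`, `true_emergence_dates` (data.frame `seal_year_id`,
#'   `emergence_date`, `NA` if the seal never emerged), `params`, `config`.
#' @export
simulate_emergence_study <- function(config = sim_config()) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, 3)
  cov <- simulate_covariates(config)
  st <- simulate_states(cov, config$true_params, seed = seeds[1])
  obs <- simulate_observations(st, config$true_params,
                               missingness = config$missingness,
                               seed = seeds[2])
  ids <- unique(obs$seal_year_id)
  em <- as.Date(vapply(ids, function(id) {
    i <- which(obs$seal_year_id == id & obs$true_state == "emerged")
    if (length(i)) as.character(min(obs$date[i])) else NA_character_
  }, character(1)))
  daily <- obs[, setdiff(names(obs), "true_state")]
  list(daily_series = daily,
       true_states = obs[, c("seal_year_id", "date", "true_state")],
       true_emergence_dates = data.frame(seal_year_id = ids,
                                         emergence_date = em,
                                         row.names = NULL,
                                         stringsAsFactors = FALSE),
       params = config$true_params,
       config = config)
}
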
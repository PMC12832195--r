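# Independent brute-force oracles for the constrained two-state model.
# Because the emerged state is absorbing, every admissible state path for a
# T-day series is determined by its transition day tau (tau = 1 means the
# seal starts emerged; tau = T + 1 means it never emerges). These oracles
# enumerate all T + 1 monotone paths directly, without any forward/Viterbi
# recursion.

# per-day emission probabilities for both states, honoring missing channels
# and the February lair constraint
oracle_emissions <- function(params, prop, peak, feb) {
  n <- length(prop)
  e <- matrix(1, n, 2)
  for (t in seq_len(n)) {
    for (s in 1:2) {
      sp <- if (s == 1) params$lair else params$emerged
      v <- 1
      if (!is.na(prop[t])) v <- v * dzoib(prop[t], sp$p0, sp$p1, sp$shape1, sp$shape2)
      if (!is.na(peak[t])) v <- v * dvonmises(peak[t], sp$mu, sp$kappa)
      e[t, s] <- v
    }
    if (feb[t]) e[t, 2] <- 0
  }
  e
}

# probability of the monotone path that transitions on day tau
oracle_path_prob <- function(tau, params, e, p) {
  T_ <- nrow(e)
  if (tau == 1) {
    w <- params$delta * prod(e[, 2])
  } else {
    w <- (1 - params$delta)
    if (tau > 2) w <- w * prod(1 - p[2:(tau - 1)])
    if (tau <= T_) w <- w * p[tau]
    w <- w * prod(e[seq_len(tau - 1), 1])
    if (tau <= T_) w <- w * prod(e[tau:T_, 2])
  }
  w
}

# total likelihood by explicit enumeration over all monotone paths
oracle_loglik <- function(params, data) {
  ll <- 0
  for (id in unique(data$seal_year_id)) {
    d <- data[data$seal_year_id == id, , drop = FALSE]
    feb <- format(d$date, "%m") == "02"
    e <- oracle_emissions(params, d$prop_ho, d$peak_hr, feb)
    eta <- rep(params$beta[["(Intercept)"]], nrow(d))
    for (tm in setdiff(names(params$beta), "(Intercept)")) {
      eta <- eta + params$beta[[tm]] * d[[tm]]
    }
    p <- plogis(eta)
    w <- vapply(seq_len(nrow(d) + 1L), oracle_path_prob, numeric(1),
                params = params, e = e, p = p)
    ll <- ll + log(sum(w))
  }
  ll
}

# most probable monotone path; ties broken toward the latest transition
oracle_viterbi <- function(params, d) {
  feb <- format(d$date, "%m") == "02"
  e <- oracle_emissions(params, d$prop_ho, d$peak_hr, feb)
  eta <- rep(params$beta[["(Intercept)"]], nrow(d))
  for (tm in setdiff(names(params$beta), "(Intercept)")) {
    eta <- eta + params$beta[[tm]] * d[[tm]]
  }
  p <- plogis(eta)
  w <- vapply(seq_len(nrow(d) + 1L), oracle_path_prob, numeric(1),
              params = params, e = e, p = p)
  tau <- max(which(w >= max(w) - 0))  # latest argmax
  states <- rep("lair", nrow(d))
  if (tau <= nrow(d)) states[tau:nrow(d)] <- "emerged"
  states
}

# random valid parameter set for property-style draws
random_params <- function(terms = character(0)) {
  m <- runif(1, 0, 0.6); q <- runif(1)
  m2 <- runif(1, 0, 0.6); q2 <- runif(1)
  beta <- setNames(rnorm(length(terms) + 1, 0, 1), c("(Intercept)", terms))
  hmm_params(
    lair = list(p0 = m * q, p1 = m * (1 - q),
                shape1 = runif(1, 0.5, 4), shape2 = runif(1, 0.5, 4),
                mu = runif(1, -pi, pi), kappa = runif(1, 0, 6)),
    emerged = list(p0 = m2 * q2, p1 = m2 * (1 - q2),
                   shape1 = runif(1, 0.5, 4), shape2 = runif(1, 0.5, 4),
                   mu = runif(1, -pi, pi), kappa = runif(1, 0, 6)),
    beta = beta, delta = runif(1, 0.05, 0.5))
}

# random short observation series (T <= 8) with missing channels and a mix
# of February / spring dates
random_series <- function(T_ = sample(1:8, 1), feb_start = runif(1) < 0.3) {
  start <- if (feb_start) as.Date("2015-02-25") else as.Date("2015-03-10")
  prop <- runif(T_)
  prop[runif(T_) < 0.15] <- 0
  prop[runif(T_) < 0.1] <- 1
  prop[runif(T_) < 0.2] <- NA
  peak <- runif(T_, -pi, pi)
  peak[is.na(prop) | prop %in% c(0, 1)] <- NA
  data.frame(seal_year_id = "s1", date = seq(start, by = "day", length.out = T_),
             prop_ho = prop, peak_hr = peak, x = rnorm(T_),
             stringsAsFactors = FALSE)
}
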
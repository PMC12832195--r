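#' Candidate transition-covariate formulas
#'
#' The fixed candidate set explored for covariate effects on the daily
#' emergence probability: a null model plus single covariates and the
#' stated interactions / additive pairs. Names refer to columns produced
#' by [annotate_series()] / [simulate_covariates()].
#'
#' @return named list of one-sided formulas.
#' @export
candidate_formulas <- function() {
  list(
    none                  = ~ 1,
    doy                   = ~ doy,
    doy_x_sex             = ~ doy * sex,
    doy_x_latitude        = ~ doy * latitude,
    daylength             = ~ daylength,
    daylength_x_latitude  = ~ daylength * latitude,
    doy_x_year            = ~ doy * year,
    sic                   = ~ sic,
    melt_early_index      = ~ melt_early_index,
    melt_cont_index       = ~ melt_cont_index,
    air_temp              = ~ air_temp,
    air_temp_daylength    = ~ air_temp + daylength,
    temp_7day             = ~ temp_7day,
    temp_7day_daylength   = ~ temp_7day + daylength,
    tdd                   = ~ tdd
  )
}

#' Number of estimable parameters of a candidate model
#'
#' The emission model contributes 13 parameters regardless of formula
#' (per-state zero/one masses and beta shapes: 8; per-state von Mises mean
#' and concentration: 4; initial-distribution probability: 1); the
#' transition model adds one coefficient per column of the design matrix
#' (intercept, main effects, interactions).
#'
#' @param formula one-sided transition formula.
#' @param data data providing the covariate columns (needed to expand
#'   factors such as `sex`).
#' @return integer parameter count.
#' @examples
#' d <- data.frame(doy = 1:4, sex = factor(c("F", "M", "F", "M")))
#' count_parameters(~ doy * sex, d) # 17
#' @export
count_parameters <- function(formula, data) {
  13L + ncol(stats::model.matrix(formula, data))
}

# ---- working <-> natural parameterization ----------------------------------
# layout: [lair m,q,log a,log b | emerged m,q,log a,log b |
#          mu_l, log k_l, mu_e, log k_e | delta logit | beta ...]

.n_fixed <- 13L

.clamp_logit <- function(p) stats::qlogis(pmin(pmax(p, 1e-8), 1 - 1e-8))

.working_from_natural <- function(params, beta_std) {
  w_state <- function(s) {
    m <- s$p0 + s$p1
    q <- if (m > 0) s$p0 / m else 0.5
    c(.clamp_logit(m), .clamp_logit(q), log(s$shape1), log(s$shape2))
  }
  c(w_state(params$lair), w_state(params$emerged),
    params$lair$mu, log(max(params$lair$kappa, 1e-8)),
    params$emerged$mu, log(max(params$emerged$kappa, 1e-8)),
    .clamp_logit(params$delta), beta_std)
}

.natural_from_working <- function(w, beta_names) {
  state <- function(off, mu, lk) {
    m <- stats::plogis(w[off + 1]); q <- stats::plogis(w[off + 2])
    list(p0 = m * q, p1 = m * (1 - q),
         shape1 = exp(w[off + 3]), shape2 = exp(w[off + 4]),
         mu = wrap_angle(mu), kappa = exp(lk))
  }
  beta <- w[(.n_fixed + 1L):length(w)]
  names(beta) <- beta_names
  structure(list(lair = state(0L, w[9], w[10]),
                 emerged = state(4L, w[11], w[12]),
                 beta = beta, delta = stats::plogis(w[13])),
            class = "hmm_params")
}

#' Daily transition-probability matrix
#'
#' The 2x2 state transition matrix for one day: the lair row transitions
#' to emerged with probability `plogis(beta . x)`, and the emerged row is
#' fixed at `[0, 1]` (absorbing).
#'
#' @param covariate_row single-row data.frame (or named list) with the
#'   covariates named in `beta`.
#' @param beta named transition coefficients (must include
#'   `"(Intercept)"`). Missing covariate values are rejected.
#' @return 2x2 row-stochastic matrix with dimnames `lair`/`emerged`.
#' @export
transition_matrix <- function(covariate_row, beta) {
  covariate_row <- as.data.frame(covariate_row)
  vals <- unlist(covariate_row[setdiff(names(beta), "(Intercept)")])
  if (length(vals) && anyNA(vals)) stop("missing covariate value in transition row")
  p <- .emergence_prob(covariate_row, beta)
  matrix(c(1 - p, 0, p, 1), 2, 2,
         dimnames = list(c("lair", "emerged"), c("lair", "emerged")))
}

# ---- likelihood machinery ---------------------------------------------------

# emission probabilities (n x 2), with missing channels contributing 1 and
# the February known-state mask zeroing the emerged column
.emission_matrix <- function(params, prop, peak, feb) {
  el <- rep(1, length(prop)); ee <- el
  for (s in c("lair", "emerged")) {
    sp <- params[[s]]
    e <- rep(1, length(prop))
    i <- !is.na(prop)
    e[i] <- dzoib(prop[i], sp$p0, sp$p1, sp$shape1, sp$shape2)
    j <- !is.na(peak)
    e[j] <- e[j] * dvonmises(peak[j], sp$mu, sp$kappa)
    if (s == "lair") el <- e else ee <- e
  }
  ee[feb] <- 0
  cbind(lair = el, emerged = ee)
}

# pad ragged seal-year sequences into T_max x n_seals index matrices
.pad_index <- function(id) {
  ids <- unique(id)
  lens <- vapply(ids, function(x) sum(id == x), integer(1))
  tmax <- max(lens)
  idx <- matrix(NA_integer_, tmax, length(ids))
  for (k in seq_along(ids)) idx[seq_len(lens[k]), k] <- which(id == ids[k])
  idx
}

# scaled forward log-likelihood over all seal-years
.forward_loglik <- function(params, em, p, idx) {
  tmax <- nrow(idx); ns <- ncol(idx)
  EL <- matrix(1, tmax, ns); EE <- matrix(1, tmax, ns); P <- matrix(0, tmax, ns)
  ok <- !is.na(idx)
  EL[ok] <- em[idx[ok], 1L]; EE[ok] <- em[idx[ok], 2L]; P[ok] <- p[idx[ok]]
  delta <- params$delta
  al <- (1 - delta) * EL[1L, ]
  ae <- delta * EE[1L, ]
  cs <- al + ae
  if (any(!is.finite(cs)) || any(cs <= 0)) return(-Inf)
  ll <- sum(log(cs)); al <- al / cs; ae <- ae / cs
  if (tmax > 1) for (t in 2:tmax) {
    pt <- P[t, ]
    ae <- (al * pt + ae) * EE[t, ]
    al <- al * (1 - pt) * EL[t, ]
    cs <- al + ae
    if (any(!is.finite(cs)) || any(cs <= 0)) return(-Inf)
    ll <- ll + sum(log(cs)); al <- al / cs; ae <- ae / cs
  }
  ll
}

#' Log-likelihood of the constrained two-state model
#'
#' Sum over seal-years of the scaled forward-algorithm log-likelihood of
#' the two-state HMM with absorbing emerged state: per-day emission is the
#' product of the zero-one-inflated beta term for the daily proportion and
#' the von Mises term for the peak hour (each missing channel contributes
#' a factor 1); February days contribute emission zero for the emerged
#' state (known-state constraint); the day-1 state weights are
#' `(1 - delta, delta)`.
#'
#' @param params an [hmm_params()] (natural scale; `beta` named by
#'   covariate columns of `data`).
#' @param data daily series data.frame with `seal_year_id`, `date`,
#'   `prop_ho`, `peak_hr` and the covariate columns named in `beta`.
#' @return scalar log-likelihood (`-Inf` for impossible data or non-finite
#'   parameters).
#' @export
hmm_loglik <- function(params, data) {
  if (!all(is.finite(unlist(params[c("lair", "emerged")]))) ||
      !all(is.finite(params$beta)) || !is.finite(params$delta)) {
    return(-Inf)
  }
  feb <- format(data$date, "%m") == "02"
  em <- .emission_matrix(params, data$prop_ho, data$peak_hr, feb)
  p <- .emergence_prob(data, params$beta)
  idx <- .pad_index(data$seal_year_id)
  .forward_loglik(params, em, p, idx)
}

.default_inits <- function(beta_names) {
  # emission inits follow previously reported per-state haul-out behavior
  # (lair ~16% of day hauled out, nocturnal and diffuse; emerged ~55%, diurnal
  # and concentrated); transition starts at a small constant daily probability
  beta <- stats::setNames(rep(0, length(beta_names)), beta_names)
  beta[["(Intercept)"]] <- -4
  hmm_params(
    lair    = list(p0 = 0.30, p1 = 0.01, shape1 = 1, shape2 = 3,
                   mu = 2.8, kappa = 1),
    emerged = list(p0 = 0.02, p1 = 0.05, shape1 = 2, shape2 = 1.6,
                   mu = 0, kappa = 3),
    beta = beta, delta = 0.05)
}

.validate_series <- function(data, formula) {
  need <- c("seal_year_id", "date", "prop_ho", "peak_hr")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data missing column(s): ", paste(miss, collapse = ", "))
  if (any(data$prop_ho < 0 | data$prop_ho > 1, na.rm = TRUE)) {
    stop("prop_ho outside [0, 1]")
  }
  for (id in unique(data$seal_year_id)) {
    d <- data$date[data$seal_year_id == id]
    if (is.unsorted(d) || (length(d) > 1 && any(diff(as.numeric(d)) != 1))) {
      stop("seal-year '", id, "' is not a contiguous sorted daily record")
    }
  }
  vars <- all.vars(formula)
  bad <- vars[vapply(vars, function(v) anyNA(data[[v]]), logical(1))]
  if (length(bad)) {
    stop("missing values in transition covariate(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the constrained two-state emergence HMM
#'
#' Maximum-likelihood fit of a two-state hidden Markov model for ringed
#' seal haul-out behavior: a "lair" state and an absorbing "emerged"
#' state, zero-one-inflated beta emission for the daily proportion hauled
#' out, von Mises emission for the circular peak haul-out hour, all
#' February days constrained to the lair state, and a logit-linear effect
#' of covariates on the daily lair-to-emerged transition probability.
#'
#' Covariates are standardized (z-scored over all seal-days) internally
#' for optimizer conditioning; coefficients are reported on both the
#' standardized and the natural covariate scale. Optimization is
#' unconstrained quasi-Newton (BFGS) over working parameters (two-stage
#' logit for the endpoint masses, logs for shapes and concentrations,
#' logit for the initial-distribution probability), with `nstarts`
#' perturbed restarts around the initial values; standard errors come from
#' the numerically differentiated Hessian at the optimum.
#'
#' @param formula one-sided formula for the transition linear predictor,
#'   e.g. `~ air_temp + daylength` (see [candidate_formulas()]).
#' @param data daily series data.frame: `seal_year_id`, `date` (contiguous
#'   per seal-year), `prop_ho`, `peak_hr`, covariate columns.
#' @param inits optional [hmm_params()] starting values (natural scale).
#' @param nstarts number of optimizer starts (first unperturbed).
#' @param seed integer seed for the restart perturbations.
#' @param standardize z-score the covariates internally? (default TRUE)
#' @param control passed to [stats::optim()] (merged over defaults
#'   `maxit = 500`, `reltol = 1e-9`).
#' @return object of class `emergence_hmm`: the fitted parameters
#'   (`params`, natural scale), working-scale estimates with standard
#'   errors, `logLik`, `npar`, `AIC`, `convergence`, standardization
#'   constants, and the data used.
#' @seealso [viterbi()], [select_models()], [predict.emergence_hmm()]
#' @export
emergence_hmm <- function(formula, data, inits = NULL, nstarts = 5,
                          seed = 1L, standardize = TRUE, control = list()) {
  .validate_series(data, formula)
  X <- stats::model.matrix(formula, data)
  beta_names <- colnames(X)
  # standardization constants (identity for the intercept)
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize && ncol(X) > 1) {
    for (j in 2:ncol(X)) {
      s <- stats::sd(X[, j])
      if (s > 0) { ctr[j] <- mean(X[, j]); scl[j] <- s }
    }
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  feb <- format(data$date, "%m") == "02"
  idx <- .pad_index(data$seal_year_id)
  prop <- data$prop_ho; peak <- data$peak_hr

  nll <- function(w) {
    if (any(!is.finite(w)) || any(abs(w) > 50)) return(1e10)
    par <- .natural_from_working(w, beta_names)
    if (!all(is.finite(unlist(par[c("lair", "emerged")])))) return(1e10)
    em <- .emission_matrix(par, prop, peak, feb)
    p <- stats::plogis(drop(Xs %*% par$beta))
    ll <- .forward_loglik(par, em, p, idx)
    if (!is.finite(ll)) 1e10 else -ll
  }

  if (is.null(inits)) inits <- .default_inits(beta_names)
  # map natural-scale initial beta onto the standardized design
  b0 <- stats::setNames(rep(0, length(beta_names)), beta_names)
  common <- intersect(names(inits$beta), beta_names)
  b0[common] <- inits$beta[common]
  bs <- b0 * scl
  bs[1] <- b0[1] + sum(b0[-1] * ctr[-1])
  w0 <- .working_from_natural(inits, bs)

  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-9), control)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(max(1, nstarts))) {
    ws <- if (r == 1) w0 else w0 + stats::rnorm(length(w0), 0, 0.3)
    opt <- tryCatch(
      stats::optim(ws, nll, method = "BFGS", control = ctl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")
  converged <- best$convergence == 0 && best$value < 1e9

  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) {
    v <- diag(vc); v[v < 0] <- NA_real_; sqrt(v)
  } else rep(NA_real_, length(best$par))

  par_nat <- .natural_from_working(best$par, beta_names)
  # back-transform transition coefficients to the natural covariate scale
  A <- diag(1 / scl)
  A[1, ] <- -ctr / scl; A[1, 1] <- 1
  bi <- (.n_fixed + 1L):length(best$par)
  beta_nat <- drop(A %*% best$par[bi])
  names(beta_nat) <- beta_names
  vcov_beta_nat <- if (!is.null(vc)) {
    v <- A %*% vc[bi, bi, drop = FALSE] %*% t(A)
    dimnames(v) <- list(beta_names, beta_names)
    v
  } else NULL
  par_nat$beta <- beta_nat

  npar <- length(best$par)
  ll <- -best$value
  structure(list(
    formula = formula, params = par_nat,
    beta_std = stats::setNames(best$par[bi], beta_names),
    working = best$par, working_se = se, vcov_working = vc,
    vcov_beta_nat = vcov_beta_nat,
    logLik = ll, npar = npar, AIC = -2 * ll + 2 * npar,
    convergence = converged,
    standardization = list(center = ctr, scale = scl, names = beta_names),
    n_seal_years = length(unique(data$seal_year_id)),
    n_obs = sum(!is.na(prop) | !is.na(peak)),
    inits = inits, data = data, seed = seed, nstarts = nstarts),
    class = "emergence_hmm")
}

#' @export
logLik.emergence_hmm <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.emergence_hmm <- function(object, scale = c("natural", "standardized"), ...) {
  scale <- match.arg(scale)
  if (scale == "natural") object$params$beta else object$beta_std
}

#' @export
vcov.emergence_hmm <- function(object, ...) {
  object$vcov_beta_nat
}

#' @export
print.emergence_hmm <- function(x, ...) {
  cat("Two-state emergence HMM (lair / absorbing emerged)\n")
  cat("  transition formula:", deparse(x$formula), "\n")
  cat(sprintf("  seal-years: %d   observed days: %d\n", x$n_seal_years, x$n_obs))
  cat(sprintf("  logLik %.2f   parameters %d   AIC %.2f   converged: %s\n",
              x$logLik, x$npar, x$AIC, x$convergence))
  cat("  transition coefficients (natural scale):\n")
  print(round(x$params$beta, 4))
  invisible(x)
}

#' @export
summary.emergence_hmm <- function(object, ...) {
  p <- object$params
  states <- do.call(rbind, lapply(c("lair", "emerged"), function(s) {
    sp <- p[[s]]
    mo <- zoib_moments(sp$p0, sp$p1, sp$shape1, sp$shape2)
    data.frame(state = s, p0 = sp$p0, p1 = sp$p1,
               shape1 = sp$shape1, shape2 = sp$shape2,
               mean_prop = mo["mean"], sd_prop = mo["sd"],
               mu = sp$mu, kappa = sp$kappa,
               peak_solar_hour = radians_to_solar_hour(sp$mu),
               row.names = NULL)
  }))
  se_nat <- if (!is.null(object$vcov_beta_nat)) {
    v <- diag(object$vcov_beta_nat); v[v < 0] <- NA; sqrt(v)
  } else rep(NA_real_, length(p$beta))
  beta <- data.frame(term = names(p$beta), estimate = unname(p$beta),
                     se = unname(se_nat))
  beta$z <- beta$estimate / beta$se
  beta$p_value <- 2 * stats::pnorm(-abs(beta$z))
  out <- list(states = states, beta = beta, delta = p$delta,
              logLik = object$logLik, npar = object$npar, AIC = object$AIC,
              convergence = object$convergence, formula = object$formula)
  class(out) <- "summary.emergence_hmm"
  out
}

#' @export
print.summary.emergence_hmm <- function(x, ...) {
  cat("Two-state emergence HMM —", deparse(x$formula), "\n\nState-dependent distributions:\n")
  print(x$states, digits = 3)
  cat("\nTransition coefficients (natural covariate scale):\n")
  print(x$beta, digits = 4)
  cat(sprintf("\nP(start emerged) = %.4f\nlogLik %.2f  k = %d  AIC %.2f  converged: %s\n",
              x$delta, x$logLik, x$npar, x$AIC, x$convergence))
  invisible(x)
}

#' Emergence-probability curve with confidence band
#'
#' Daily emergence probability `plogis(x' beta)` over new covariate
#' values, with a 95% delta-method confidence interval computed on the
#' logit scale and back-transformed. Rows whose covariates fall outside
#' the range observed in the fitting data are flagged as extrapolation.
#'
#' @param object a fitted `emergence_hmm`.
#' @param newdata data.frame of covariate values (all formula variables).
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return `newdata` with columns `p`, `lower`, `upper`, `extrapolated`.
#' @export
predict.emergence_hmm <- function(object, newdata, level = 0.95, ...) {
  X <- stats::model.matrix(object$formula, newdata)
  st <- object$standardization
  Xs <- sweep(sweep(X, 2, st$center), 2, st$scale, "/")
  eta <- drop(Xs %*% object$beta_std)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (!is.null(object$vcov_working)) {
    bi <- (.n_fixed + 1L):length(object$working)
    V <- object$vcov_working[bi, bi, drop = FALSE]
    se <- sqrt(pmax(rowSums((Xs %*% V) * Xs), 0))
  } else {
    se <- rep(NA_real_, length(eta))
  }
  vars <- all.vars(object$formula)
  extrap <- rep(FALSE, nrow(newdata))
  for (v in vars) {
    ov <- object$data[[v]]
    if (is.numeric(ov)) {
      extrap <- extrap | newdata[[v]] < min(ov) | newdata[[v]] > max(ov)
    }
  }
  out <- newdata
  out$p <- stats::plogis(eta)
  out$lower <- stats::plogis(eta - z * se)
  out$upper <- stats::plogis(eta + z * se)
  out$extrapolated <- extrap
  out
}

#' Simulate observation series from a fitted model
#'
#' Draws new latent state paths and daily observations from the fitted
#' parameters over the covariate trajectories of the fitting data (or
#' `newdata`), e.g. for parametric-bootstrap checks.
#'
#' @param object a fitted `emergence_hmm`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param newdata optional covariate table (defaults to the fitting data).
#' @param ... unused.
#' @return list of `nsim` data.frames shaped like the fitting data.
#' @export
simulate.emergence_hmm <- function(object, nsim = 1, seed = 1L,
                                   newdata = NULL, ...) {
  cov <- if (is.null(newdata)) object$data else newdata
  cov <- cov[, setdiff(names(cov), c("prop_ho", "peak_hr")), drop = FALSE]
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 2 * nsim)
  lapply(seq_len(nsim), function(i) {
    st <- simulate_states(cov, object$params, seed = seeds[2 * i - 1])
    simulate_observations(st, object$params,
                          missingness = list(p_gap_start = 0, gap_mean = 1),
                          seed = seeds[2 * i])
  })
}

#' Fit and rank the candidate model set
#'
#' Fits each candidate transition formula on the same data and ranks the
#' fits by AIC (`delta_aic = AIC - min(AIC)`), ties broken by fewer
#' parameters. Failed fits are listed with a flag and excluded from the
#' delta-AIC base.
#'
#' @param data daily series data.frame (see [emergence_hmm()]).
#' @param formulas named list of one-sided formulas (default the full
#'   candidate set restricted to columns present in `data`).
#' @param ... passed to [emergence_hmm()].
#' @return data.frame: `model`, `k`, `logLik`, `AIC`, `delta_aic`,
#'   `converged`, `best`; sorted by AIC. The fitted objects are attached
#'   as attribute `"fits"`.
#' @export
select_models <- function(data, formulas = NULL, ...) {
  if (is.null(formulas)) {
    formulas <- Filter(function(f) all(all.vars(f) %in% names(data)),
                       candidate_formulas())
  }
  fits <- lapply(formulas, function(f) {
    tryCatch(emergence_hmm(f, data, ...), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  tab <- data.frame(
    model = names(formulas),
    k = vapply(formulas, function(f) count_parameters(f, data), integer(1)),
    logLik = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$logLik, numeric(1)), NA_real_),
    AIC = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$AIC, numeric(1)),
    converged = ok & vapply(fits, function(f)
      if (inherits(f, "error")) FALSE else f$convergence, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  base <- suppressWarnings(min(tab$AIC[tab$converged], na.rm = TRUE))
  tab$delta_aic <- tab$AIC - base
  tab <- tab[order(is.na(tab$AIC), tab$AIC, tab$k), , drop = FALSE]
  tab$best <- seq_len(nrow(tab)) == 1L & tab$converged
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
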
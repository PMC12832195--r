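#' Viterbi decoding of the most probable state path
#'
#' Dynamic-programming decode of the fitted two-state model, honoring the
#' absorbing-emerged and February known-state constraints (so every
#' decoded path is monotone: lair days, then emerged days). Missing
#' observation channels contribute an emission factor of 1. Ties are
#' broken toward the later transition (staying in the lair), a
#' conservative emergence dating choice.
#'
#' @param fit a converged [emergence_hmm()] fit.
#' @param data daily series to decode (defaults to the fitting data).
#' @return data.frame: `seal_year_id`, `date`, `state`
#'   (`"lair"`/`"emerged"`).
#' @export
viterbi <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "emergence_hmm"))
  if (is.null(data)) data <- fit$data
  params <- fit$params
  feb <- format(data$date, "%m") == "02"
  em <- .emission_matrix(params, data$prop_ho, data$peak_hr, feb)
  p <- .emergence_prob(data, params$beta)
  out_state <- rep(NA_character_, nrow(data))
  for (id in unique(data$seal_year_id)) {
    i <- which(data$seal_year_id == id)
    out_state[i] <- .viterbi_one(params$delta, em[i, , drop = FALSE], p[i])
  }
  data.frame(seal_year_id = data$seal_year_id, date = data$date,
             state = out_state, stringsAsFactors = FALSE)
}

# single-series Viterbi in log space; monotone paths only, ties -> later
# transition (prefer lair)
.viterbi_one <- function(delta, em, p) {
  n <- nrow(em)
  le_l <- log(em[, 1L]); le_e <- log(em[, 2L])
  vl <- log(1 - delta) + le_l[1L]
  ve <- log(delta) + le_e[1L]
  # from[t] records whether the emerged score at t came from a lair day t-1
  from_lair <- logical(n)
  if (n > 1) for (t in 2:n) {
    cand_trans <- vl + log(p[t])        # transition into day t
    cand_stay <- ve                     # already emerged
    # tie -> prefer the transition at t (i.e. later transition overall)
    from_lair[t] <- cand_trans >= cand_stay
    ve <- max(cand_trans, cand_stay) + le_e[t]
    vl <- vl + log(1 - p[t]) + le_l[t]
  }
  # final tie -> prefer lair (no transition at all)
  states <- rep("lair", n)
  if (ve > vl) {
    # backtrack: find the transition day
    tau <- 1L
    if (n > 1) {
      t <- n
      while (t >= 2) {
        if (from_lair[t]) { tau <- t; break }
        t <- t - 1L
        if (t == 1L) tau <- 1L
      }
    }
    states[tau:n] <- "emerged"
  }
  states
}

#' Extract per-seal emergence dates from decoded paths
#'
#' The emergence date of a seal-year is the first day its decoded state is
#' "emerged". Seal-years decoded entirely in the lair state are reported
#' separately with coverage diagnostics (first/last observed date).
#'
#' @param decoded output of [viterbi()].
#' @param series the decoded daily series (for covariates at emergence);
#'   optional.
#' @return data.frame of emerged seal-years: `seal_year_id`,
#'   `emergence_date`, `emergence_doy`, `year`, plus `latitude`,
#'   `longitude`, and covariates at the emergence date when `series` is
#'   given. Never-emerged seal-years are attached as attribute
#'   `"not_emerged"`.
#' @export
emergence_dates <- function(decoded, series = NULL) {
  ids <- unique(decoded$seal_year_id)
  rows <- list(); none <- list()
  for (id in ids) {
    d <- decoded[decoded$seal_year_id == id, , drop = FALSE]
    i <- which(d$state == "emerged")
    if (length(i)) {
      ed <- min(d$date[i])
      r <- data.frame(seal_year_id = id, emergence_date = ed,
                      emergence_doy = as.integer(format(ed, "%j")),
                      year = as.integer(format(ed, "%Y")),
                      stringsAsFactors = FALSE)
      if (!is.null(series)) {
        sr <- series[series$seal_year_id == id & series$date == ed, , drop = FALSE]
        for (v in intersect(c("latitude", "longitude", "air_temp", "daylength"),
                            names(sr))) {
          r[[v]] <- if (nrow(sr)) sr[[v]][1] else NA_real_
        }
      }
      rows[[id]] <- r
    } else {
      none[[id]] <- data.frame(seal_year_id = id,
                               first_date = min(d$date), last_date = max(d$date),
                               stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seal_year_id = character(0), emergence_date = as.Date(character(0)),
               emergence_doy = integer(0), year = integer(0))
  rownames(out) <- NULL
  attr(out, "not_emerged") <- if (length(none)) {
    nr <- do.call(rbind, none); rownames(nr) <- NULL; nr
  } else NULL
  out
}

#' State-conditional haul-out summaries
#'
#' Mean and SD of the daily proportion hauled out (in percent) and the
#' circular mean peak haul-out hour for the records assigned to each
#' decoded state, computed over non-missing observations only.
#'
#' @param decoded output of [viterbi()].
#' @param series the daily series carrying `prop_ho` and `peak_hr`.
#' @return data.frame, one row per state: `state`, `n_prop`,
#'   `mean_prop_pct`, `sd_prop_pct`, `n_peak`, `peak_mean_rad`,
#'   `peak_solar_hour`.
#' @export
state_summaries <- function(decoded, series) {
  key_d <- paste(decoded$seal_year_id, decoded$date)
  key_s <- paste(series$seal_year_id, series$date)
  st <- decoded$state[match(key_s, key_d)]
  out <- lapply(c("lair", "emerged"), function(s) {
    i <- which(st == s)
    pr <- series$prop_ho[i]; pk <- series$peak_hr[i]
    pr <- pr[!is.na(pr)]; pk <- pk[!is.na(pk)]
    mu <- circular_mean(pk)
    data.frame(state = s, n_prop = length(pr),
               mean_prop_pct = if (length(pr)) 100 * mean(pr) else NA_real_,
               sd_prop_pct = if (length(pr) > 1) 100 * stats::sd(pr) else NA_real_,
               n_peak = length(pk),
               peak_mean_rad = mu,
               peak_solar_hour = if (is.na(mu)) NA_real_ else radians_to_solar_hour(mu),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Leave-one-out sensitivity of emergence dates
#'
#' Re-fits the model with each seal sequentially removed and re-decodes
#' the remaining seal-years, recording every remaining seal's emergence
#' date in each iteration. Reports, per seal-year, the SD of its
#' emergence DOY across iterations and the count of iterations in which
#' it was decoded as never emerging. By default all seal-years sharing a
#' seal (two-year tags) are removed together.
#'
#' @param fit a fitted [emergence_hmm()] (its data and formula are reused).
#' @param by_seal treat `seal_year_id`s sharing the prefix before `"_"` as
#'   one seal and remove them jointly (default TRUE).
#' @param nstarts optimizer restarts per refit (default 2; refits start
#'   from the full-data estimates, which are already close).
#' @param ... passed to [emergence_hmm()].
#' @return data.frame: `seal_year_id`, `n_iterations`, `mean_doy`,
#'   `sd_days`, `n_no_emergence`. Failed refits are dropped with a
#'   warning. The per-iteration date matrix is attached as attribute
#'   `"dates"`.
#' @export
leave_one_out <- function(fit, by_seal = TRUE, nstarts = 2, ...) {
  data <- fit$data
  ids <- unique(data$seal_year_id)
  if (length(ids) < 3) stop("leave-one-out needs at least 3 seal-years")
  seal_of <- if (by_seal) sub("_.*$", "", ids) else ids
  units <- unique(seal_of)
  doy_mat <- matrix(NA_real_, nrow = length(ids), ncol = length(units),
                    dimnames = list(ids, units))
  never <- matrix(FALSE, nrow = length(ids), ncol = length(units),
                  dimnames = list(ids, units))
  ok <- logical(length(units)); names(ok) <- units
  for (u in units) {
    keep_ids <- ids[seal_of != u]
    sub <- data[data$seal_year_id %in% keep_ids, , drop = FALSE]
    ref <- tryCatch(
      emergence_hmm(fit$formula, sub, inits = fit$params,
                    nstarts = nstarts, seed = fit$seed, ...),
      error = function(e) NULL)
    if (is.null(ref) || !ref$convergence) {
      warning("refit without seal '", u, "' failed to converge; iteration excluded")
      next
    }
    ok[u] <- TRUE
    ed <- emergence_dates(viterbi(ref, sub))
    m <- match(ed$seal_year_id, ids)
    doy_mat[m, u] <- ed$emergence_doy
    ne <- attr(ed, "not_emerged")
    if (!is.null(ne)) never[match(ne$seal_year_id, ids), u] <- TRUE
  }
  doy_mat <- doy_mat[, ok, drop = FALSE]
  never <- never[, ok, drop = FALSE]
  res <- data.frame(
    seal_year_id = ids,
    n_iterations = rowSums(!is.na(doy_mat)),
    mean_doy = rowMeans(doy_mat, na.rm = TRUE),
    sd_days = apply(doy_mat, 1, stats::sd, na.rm = TRUE),
    n_no_emergence = rowSums(never),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "dates") <- doy_mat
  res
}
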
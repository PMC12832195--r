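#' Isolate haul-out behavior from surfacing noise in hourly percent-dry data
#'
#' Satellite tags record the percent of each hour the wet/dry sensor was
#' dry. Head- or back-mounted tags also read "dry" when the seal surfaces
#' to breathe, so raw percent-dry overstates haul-out. This filter keeps an
#' hour's value as percent hauled out if the hour was at least 50% dry, or
#' if it was under 50% dry but chronologically adjacent to an hour at least
#' 95% dry; all other hours are set to 0%. Adjacency is evaluated only
#' within a contiguous run of hourly records: a neighbor across a
#' transmission gap does not qualify, and edge hours consider only the
#' neighbors they have.
#'
#' @param hourly data.frame with columns `seal_year_id`, `timestamp`
#'   (`POSIXct`, strictly increasing within seal-year), `percent_dry`
#'   (0-100). A bare numeric vector is also accepted and treated as one
#'   contiguous hourly record.
#' @return the input with `percent_dry` replaced by a `percent_ho` column
#'   (percent hauled out), or a numeric vector if a vector was given.
#' @examples
#' apply_haulout_filter(c(40, 96, 40)) # both 40s kept: adjacent to >= 95
#' apply_haulout_filter(c(40, 80, 40)) # -> 0, 80, 0
#' @export
apply_haulout_filter <- function(hourly) {
  if (is.numeric(hourly)) {
    return(.irani_filter(hourly))
  }
  .check_hourly(hourly)
  if (nrow(hourly) == 0) {
    hourly$percent_ho <- numeric(0)
    hourly$percent_dry <- NULL
    return(hourly)
  }
  out <- hourly
  out$percent_ho <- NA_real_
  for (id in unique(out$seal_year_id)) {
    i <- which(out$seal_year_id == id)
    ts <- out$timestamp[i]
    # split at transmission gaps (> 1 h between consecutive records)
    gap <- c(FALSE, diff(as.numeric(ts)) > 3600 + 1)
    run <- cumsum(gap)
    for (r in unique(run)) {
      j <- i[run == r]
      out$percent_ho[j] <- .irani_filter(out$percent_dry[j])
    }
  }
  out$percent_dry <- NULL
  out
}

.irani_filter <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  keep <- x >= 50
  if (n > 1) {
    nb95 <- c(x[-1] >= 95, FALSE) | c(FALSE, x[-n] >= 95)
    keep <- keep | (x < 50 & nb95)
  }
  ifelse(keep, x, 0)
}

.check_hourly <- function(hourly) {
  need <- c("seal_year_id", "timestamp", "percent_dry")
  miss <- setdiff(need, names(hourly))
  if (length(miss)) {
    stop("hourly timeline missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(hourly$percent_dry < 0 | hourly$percent_dry > 100)
  if (length(bad)) {
    stop("percent_dry outside [0, 100] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Daily proportion of time hauled out
#'
#' Sum of the 24 hourly percents hauled out divided by 24 (and 100). Days
#' without a full 24 hours of data are treated as missing to avoid bias
#' from partially transmitted days.
#'
#' @param percents numeric vector of hourly percent-hauled-out values for
#'   one calendar day.
#' @return proportion in \[0, 1\], or `NA` if fewer than 24 values.
#' @export
daily_proportion <- function(percents) {
  percents <- percents[!is.na(percents)]
  if (length(percents) != 24) return(NA_real_)
  sum(percents / 100) / 24
}

#' Mean local solar hour
#'
#' Converts a UTC hour to mean local solar time using the longitude offset
#' of 15 degrees per hour. The equation of time (at most ~15 min) is
#' ignored; it is small against hour-long bins.
#'
#' @param utc_hour hour of day, 0-24 (fractions allowed).
#' @param longitude degrees east, normalized to (-180, 180\].
#' @return solar hour in `[0, 24)`.
#' @examples
#' solar_hour(22, -150) # 12
#' @export
solar_hour <- function(utc_hour, longitude) {
  (utc_hour + longitude / 15) %% 24
}

#' Weighted circular peak haul-out hour for one day
#'
#' Each of the day's 24 hours is mapped to an angle via its solar midpoint,
#' `theta_h = 2*pi*(solar_mid - 12)/24` wrapped to `[-pi, pi)` (solar noon
#' = 0), and the peak hour is the circular mean of these angles weighted by
#' the hourly percent hauled out. Days on which the seal was hauled out 0%
#' or 100% of the time carry no diel information and return `NA`, as does
#' an exactly balanced (zero-resultant) day.
#'
#' @param percents 24 hourly percent-hauled-out values, indexed by UTC hour
#'   0-23.
#' @param longitude degrees east of the seal that day.
#' @return peak hour in radians `[-pi, pi)`, or `NA`.
#' @export
peak_haulout_hour <- function(percents, longitude) {
  if (length(percents) != 24 || anyNA(percents)) return(NA_real_)
  if (sum(percents) == 0 || all(percents == 100)) return(NA_real_)
  sh <- solar_hour(0:23 + 0.5, longitude)
  theta <- solar_hour_to_radians(sh)
  circular_mean(theta, w = percents)
}

#' Error-weighted daily location
#'
#' Collapses within-day Argos fixes to one location per day, weighting each
#' fix by the inverse of its error radius (missing radius counts as weight
#' 1). Longitudes are averaged on the circle so tracks near the
#' antimeridian do not wrap to the wrong hemisphere.
#'
#' @param fixes data.frame with columns `latitude`, `longitude`, and
#'   optionally `error_radius` (> 0).
#' @return list with `latitude`, `longitude`, `n_fixes`,
#'   `mean_error_weight`, or `NULL` for zero fixes.
#' @export
average_daily_location <- function(fixes) {
  if (is.null(fixes) || nrow(fixes) == 0) return(NULL)
  w <- if ("error_radius" %in% names(fixes)) {
    ifelse(is.na(fixes$error_radius), 1, 1 / fixes$error_radius)
  } else {
    rep(1, nrow(fixes))
  }
  stopifnot(all(w > 0))
  lat <- sum(w * fixes$latitude) / sum(w)
  lon_rad <- fixes$longitude * pi / 180
  lon <- atan2(sum(w * sin(lon_rad)), sum(w * cos(lon_rad))) * 180 / pi
  if (lon <= -180) lon <- lon + 360
  list(latitude = lat, longitude = lon,
       n_fixes = nrow(fixes), mean_error_weight = mean(w))
}

#' Build contiguous daily series from hourly timelines and locations
#'
#' Converts filtered hourly haul-out timelines into the two daily observed
#' variables (proportion of day hauled out; peak haul-out hour) on a
#' contiguous daily grid from each seal-year's first to last transmission
#' date. Missing dates are inserted with missing observations (never
#' interpolated). Daily locations are forward-filled from the previous
#' known location; leading gaps are back-filled from the first available
#' location so every day has coordinates.
#'
#' @param hourly_ho filtered hourly data.frame (`seal_year_id`,
#'   `timestamp`, `percent_ho`), e.g. from [apply_haulout_filter()].
#' @param locations data.frame of daily locations (`seal_year_id`, `date`,
#'   `latitude`, `longitude`); at most one row per seal-year-day.
#' @param metadata optional data.frame (`seal_year_id`, `age_class`, `sex`)
#'   joined onto the output.
#' @return data.frame (one row per seal-year-day): `seal_year_id`, `date`,
#'   `prop_ho`, `peak_hr`, `latitude`, `longitude`, plus metadata columns.
#' @export
build_daily_series <- function(hourly_ho, locations, metadata = NULL) {
  stopifnot(all(c("seal_year_id", "timestamp", "percent_ho") %in% names(hourly_ho)))
  out <- list()
  for (id in unique(hourly_ho$seal_year_id)) {
    h <- hourly_ho[hourly_ho$seal_year_id == id, , drop = FALSE]
    day <- as.Date(h$timestamp, tz = "UTC")
    dates <- seq(min(day), max(day), by = "day")
    prop <- peak <- rep(NA_real_, length(dates))
    utc_h <- as.integer(format(h$timestamp, "%H", tz = "UTC"))
    loc <- locations[locations$seal_year_id == id, , drop = FALSE]
    if (nrow(loc) == 0) {
      stop("seal-year '", id, "' has no location estimates and no fallback")
    }
    loc <- loc[order(loc$date), , drop = FALSE]
    lat <- lon <- rep(NA_real_, length(dates))
    m <- match(as.character(dates), as.character(loc$date))
    lat[!is.na(m)] <- loc$latitude[m[!is.na(m)]]
    lon[!is.na(m)] <- loc$longitude[m[!is.na(m)]]
    lat <- .fill_locf(lat)
    lon <- .fill_locf(lon)
    for (k in seq_along(dates)) {
      i <- which(day == dates[k])
      if (length(i) == 0) next
      pct <- rep(NA_real_, 24)
      pct[utc_h[i] + 1L] <- h$percent_ho[i]
      if (anyNA(pct)) next  # not a full 24-h day
      prop[k] <- daily_proportion(pct)
      peak[k] <- peak_haulout_hour(pct, lon[k])
    }
    d <- data.frame(seal_year_id = id, date = dates,
                    prop_ho = prop, peak_hr = peak,
                    latitude = lat, longitude = lon,
                    stringsAsFactors = FALSE)
    out[[id]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(metadata)) {
    res <- merge(res, metadata, by = "seal_year_id", all.x = TRUE, sort = FALSE)
    res <- res[order(res$seal_year_id, res$date), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

# forward-fill then back-fill leading NAs
.fill_locf <- function(x) {
  if (all(is.na(x))) return(x)
  idx <- cumsum(!is.na(x))
  filled <- c(NA_real_, x[!is.na(x)])[idx + 1L]
  first <- x[which(!is.na(x))[1]]
  filled[is.na(filled)] <- first
  filled
}
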
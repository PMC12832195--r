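#' Astronomical day length
#'
#' Hours of daylight from day of year and latitude, via the standard
#' solar-declination approximation
#' `delta = -23.44 * cos(2*pi*(doy + 10)/365.25)` (degrees) and the sunrise
#' hour-angle equation `daylength = (24/pi) * acos(-tan(phi) * tan(delta))`
#' with the cosine argument clamped to \[-1, 1\] so polar night yields 0 h
#' and polar day 24 h.
#'
#' @param doy day of year, 1-366.
#' @param latitude degrees north, in \[-90, 90\].
#' @return day length in hours, in \[0, 24\].
#' @examples
#' daylength(150, 70.5) # polar day: 24
#' @export
daylength <- function(doy, latitude) {
  stopifnot(all(doy >= 1 & doy <= 366), all(abs(latitude) <= 90))
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365.25)
  x <- -tan(latitude * pi / 180) * tan(decl)
  x <- pmin(pmax(x, -1), 1)
  (24 / pi) * acos(x)
}

#' Cumulative thawing degree days
#'
#' Number of days since 1 April (inclusive) with mean daily air
#' temperature at or above 0 degrees C, evaluated at each requested date.
#' Days before 1 April score 0. Missing temperatures do not count.
#'
#' @param dates vector of `Date`s (one seal-year; sorted).
#' @param temps daily mean temperatures aligned with `dates`.
#' @return integer vector of counts aligned with `dates`.
#' @export
thawing_degree_days <- function(dates, temps) {
  stopifnot(length(dates) == length(temps))
  yr <- as.integer(format(dates, "%Y"))
  out <- integer(length(dates))
  for (y in unique(yr)) {
    i <- which(yr == y)
    apr1 <- as.Date(sprintf("%d-04-01", y))
    thaw <- !is.na(temps[i]) & temps[i] >= 0 & dates[i] >= apr1
    out[i] <- cumsum(thaw)
  }
  out
}

#' Trailing 7-day rolling mean temperature
#'
#' Mean of the available daily temperatures in the trailing window
#' `[date - window + 1, date]`. Partial windows use whatever days are
#' available (transmission gaps are pervasive and the transition model
#' needs a covariate every day); a window with no data is missing.
#'
#' @param dates sorted `Date` vector for one seal-year.
#' @param temps temperatures aligned with `dates` (`NA` allowed).
#' @param window window length in days (default 7).
#' @return numeric vector of rolling means aligned with `dates`.
#' @export
rolling_mean_temp <- function(dates, temps, window = 7) {
  stopifnot(length(dates) == length(temps), window >= 1)
  n <- length(dates)
  out <- rep(NA_real_, n)
  dn <- as.numeric(dates)
  for (k in seq_len(n)) {
    in_win <- dn >= dn[k] - (window - 1) & dn <= dn[k]
    v <- temps[in_win & !is.na(temps)]
    if (length(v)) out[k] <- mean(v)
  }
  out
}

#' Melt-progression index
#'
#' Days since snow/ice melt onset: the observation's day of year minus the
#' melt-onset day of year at the seal's location. Negative values are days
#' before melt (e.g. -5 = five days before melt onset), positive after.
#'
#' @param date observation `Date` (or DOY integer).
#' @param melt_onset_doy melt onset day of year at that location.
#' @return signed days.
#' @export
melt_index <- function(date, melt_onset_doy) {
  doy <- if (inherits(date, "Date")) as.integer(format(date, "%j")) else as.integer(date)
  doy - melt_onset_doy
}

#' Construct a gridded covariate
#'
#' In-memory container for a regular latitude/longitude grid of a daily
#' (or static) environmental field, as read from long-format CSV or built
#' directly. Values are stored as an array `[lat, lon, time]`; static
#' fields (e.g. melt-onset DOY) have a single time slice.
#'
#' @param lat,lon monotone increasing cell-center coordinate vectors.
#' @param values array `length(lat) x length(lon) x n_times` (a matrix is
#'   promoted to one time slice). `NA` cells allowed (e.g. coastal masks).
#' @param dates `Date` vector of time slices, or `NULL` for a static grid.
#' @param variable name of the field.
#' @return object of class `covariate_grid`.
#' @export
covariate_grid <- function(lat, lon, values, dates = NULL, variable = "value") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(lat), dim(values)[2] == length(lon),
            !is.unsorted(lat), !is.unsorted(lon))
  if (!is.null(dates)) {
    stopifnot(length(dates) == dim(values)[3])
    if (length(dates) > 1 && any(diff(as.numeric(dates)) != 1)) {
      stop("grid time axis must be daily and contiguous")
    }
  }
  structure(list(lat = lat, lon = lon, values = values,
                 dates = dates, variable = variable),
            class = "covariate_grid")
}

#' Extract a gridded covariate at daily seal locations
#'
#' Looks up, for each row of a daily series, the grid cell nearest the
#' seal's location (nearest cell center) on the matching date (static
#' grids ignore the date). Missing cells are resolved by the nearest valid
#' cell within `fill_radius` cells; locations outside the grid bounding box
#' (by more than one cell) yield missing with a warning.
#'
#' @param series daily series data.frame with `date`, `latitude`,
#'   `longitude`.
#' @param grid a [covariate_grid()].
#' @param fill_radius max Chebyshev radius (in cells) searched for a valid
#'   neighbor when the matched cell is missing. Default 2.
#' @return numeric vector of extracted values aligned with `series` rows.
#' @export
extract_at <- function(series, grid, fill_radius = 2) {
  stopifnot(inherits(grid, "covariate_grid"))
  n <- nrow(series)
  out <- rep(NA_real_, n)
  dlat <- if (length(grid$lat) > 1) min(diff(grid$lat)) else 1
  dlon <- if (length(grid$lon) > 1) min(diff(grid$lon)) else 1
  n_out <- 0L
  for (k in seq_len(n)) {
    la <- series$latitude[k]; lo <- series$longitude[k]
    if (la < min(grid$lat) - dlat || la > max(grid$lat) + dlat ||
        lo < min(grid$lon) - dlon || lo > max(grid$lon) + dlon) {
      n_out <- n_out + 1L
      next
    }
    i <- which.min(abs(grid$lat - la))
    j <- which.min(abs(grid$lon - lo))
    t_idx <- 1L
    if (!is.null(grid$dates)) {
      t_idx <- match(as.character(series$date[k]), as.character(grid$dates))
      if (is.na(t_idx)) next
    }
    v <- grid$values[i, j, t_idx]
    if (is.na(v) && fill_radius > 0) {
      for (r in seq_len(fill_radius)) {
        ii <- max(1, i - r):min(length(grid$lat), i + r)
        jj <- max(1, j - r):min(length(grid$lon), j + r)
        ring <- grid$values[ii, jj, t_idx]
        if (any(!is.na(ring))) {
          # nearest valid cell within the ring by great-circle-free metric
          cand <- expand.grid(ii = ii, jj = jj)
          cand$val <- as.vector(ring)
          cand <- cand[!is.na(cand$val), , drop = FALSE]
          d2 <- (grid$lat[cand$ii] - la)^2 + (grid$lon[cand$jj] - lo)^2
          v <- cand$val[which.min(d2)]
          break
        }
      }
    }
    out[k] <- v
  }
  if (n_out > 0) {
    warning(n_out, " location(s) outside grid bounding box; values set missing")
  }
  out
}

#' Annotate a daily series with transition-model covariates
#'
#' Adds the derived covariate columns the candidate transition models use:
#' day of year (`doy`), `year`, `daylength` (h), 7-day rolling mean
#' temperature (`temp_7day`), cumulative thawing degree days (`tdd`), and,
#' when the corresponding grids are supplied, air temperature (`air_temp`),
#' sea-ice concentration (`sic`) and melt indices (`melt_early_index`,
#' `melt_cont_index`). An existing `air_temp` column (e.g. from the
#' synthetic generator) is used directly for the temperature-derived
#' covariates.
#'
#' @param series daily series data.frame (see [build_daily_series()]).
#' @param temp_grid,sic_grid optional daily [covariate_grid()]s of air
#'   temperature (deg C) and sea-ice concentration (0-1).
#' @param melt_early_grid,melt_cont_grid optional static
#'   [covariate_grid()]s of early / continuous melt-onset DOY.
#' @param fill_radius passed to [extract_at()].
#' @return the series with covariate columns appended.
#' @export
annotate_series <- function(series, temp_grid = NULL, sic_grid = NULL,
                            melt_early_grid = NULL, melt_cont_grid = NULL,
                            fill_radius = 2) {
  stopifnot(all(c("seal_year_id", "date", "latitude") %in% names(series)))
  series$doy <- as.integer(format(series$date, "%j"))
  series$year <- as.integer(format(series$date, "%Y"))
  series$daylength <- daylength(series$doy, series$latitude)
  if (!is.null(temp_grid)) {
    series$air_temp <- extract_at(series, temp_grid, fill_radius)
  }
  if (is.null(series$air_temp)) {
    stop("no air temperature available: supply 'temp_grid' or an 'air_temp' column")
  }
  series$temp_7day <- NA_real_
  series$tdd <- NA_integer_
  for (id in unique(series$seal_year_id)) {
    i <- which(series$seal_year_id == id)
    series$temp_7day[i] <- rolling_mean_temp(series$date[i], series$air_temp[i])
    series$tdd[i] <- thawing_degree_days(series$date[i], series$air_temp[i])
  }
  if (!is.null(sic_grid)) {
    series$sic <- extract_at(series, sic_grid, fill_radius)
  }
  if (!is.null(melt_early_grid)) {
    onset <- extract_at(series, melt_early_grid, fill_radius)
    series$melt_early_index <- melt_index(series$date, onset)
  }
  if (!is.null(melt_cont_grid)) {
    onset <- extract_at(series, melt_cont_grid, fill_radius)
    series$melt_cont_index <- melt_index(series$date, onset)
  }
  series
}
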
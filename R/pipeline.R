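#' Read and write the package's CSV schemas
#'
#' Plain-CSV codecs for the pipeline artifacts. Missing values are
#' written as empty cells (never sentinel numbers); dates are ISO-8601;
#' peak hours are radians with solar noon at 0. `read_hourly_csv`
#' validates the schema and reports offending row numbers.
#'
#' @param path file path.
#' @param x table to write.
#' @return the table (readers), or `path` invisibly (writers).
#' @name codecs
NULL

#' @rdname codecs
#' @export
read_hourly_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("seal_year_id", "timestamp", "percent_dry")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("hourly CSV missing column(s): ", paste(miss, collapse = ", "))
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                           "%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS",
                                           "%Y-%m-%d %H:%M",
                                           "%Y-%m-%d"))
  bad <- which(is.na(d$percent_dry) | d$percent_dry < 0 | d$percent_dry > 100)
  if (length(bad)) {
    stop("percent_dry outside [0, 100] (or missing) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  d
}

#' @rdname codecs
#' @export
write_hourly_csv <- function(x, path) {
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname codecs
#' @export
read_daily_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("seal_year_id", "date", "prop_ho", "peak_hr")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("daily CSV missing column(s): ", paste(miss, collapse = ", "))
  d$date <- as.Date(d$date)
  bad <- which(!is.na(d$prop_ho) & (d$prop_ho < 0 | d$prop_ho > 1))
  if (length(bad)) {
    stop("prop_ho outside [0, 1] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  d
}

#' @rdname codecs
#' @export
write_daily_csv <- function(x, path) {
  x$date <- format(x$date)
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname codecs
#' @export
read_grid_csv <- function(path, variable = "value") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("grid CSV missing column(s): ", paste(miss, collapse = ", "))
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  dates <- NULL
  if ("date" %in% names(d) && any(!is.na(d$date) & d$date != "")) {
    dates <- sort(unique(as.Date(d$date)))
    vals <- array(NA_real_, c(length(lat), length(lon), length(dates)))
    i <- match(d$lat, lat); j <- match(d$lon, lon)
    k <- match(as.Date(d$date), dates)
    vals[cbind(i, j, k)] <- d$value
  } else {
    vals <- array(NA_real_, c(length(lat), length(lon), 1L))
    vals[cbind(match(d$lat, lat), match(d$lon, lon), 1L)] <- d$value
  }
  covariate_grid(lat, lon, vals, dates, variable)
}

#' Run the end-to-end emergence analysis
#'
#' Orchestrates the pipeline stages in dependency order:
#' simulate (optional) -> prep (hourly to daily, optional) -> annotate ->
#' fit -> decode -> trends (optional) -> leave-one-out (optional). Writes
#' each stage's artifact as CSV under `out_dir` and returns a manifest
#' with content hashes, so identical inputs and seed give identical runs.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{sim}{a [sim_config()] to generate synthetic data, OR}
#'     \item{daily_series}{an existing daily series data.frame;}
#'     \item{formula}{transition formula (default `~ air_temp + daylength`);}
#'     \item{from_hourly}{logical: re-derive the daily observations from a
#'       rendered hourly timeline through the preprocessing stage
#'       (synthetic runs only; default FALSE);}
#'     \item{run_trends}{fit post-hoc latitude/year trends (default TRUE);}
#'     \item{run_loo}{run leave-one-out sensitivity (default FALSE);}
#'     \item{nstarts, seed}{optimizer options;}
#'     \item{out_dir}{output directory (default `tempfile()`).}
#'   }
#' @return list: `fit`, `decoded`, `emergence`, `summaries`, `trends`,
#'   `loo`, `manifest` (data.frame of artifact paths and MD5 hashes),
#'   `truth` (synthetic runs).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(formula = ~ air_temp + daylength,
                                from_hourly = FALSE, run_trends = TRUE,
                                run_loo = FALSE, nstarts = 5, seed = 1L,
                                out_dir = tempfile("emergence_run_")),
                           config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(cfg$sim)) {
    sim <- simulate_emergence_study(cfg$sim)
    daily <- sim$daily_series
    truth <- sim[c("true_states", "true_emergence_dates", "params")]
    if (isTRUE(cfg$from_hourly)) {
      hourly <- render_hourly(daily, seed = cfg$seed)
      locs <- unique(daily[, c("seal_year_id", "latitude", "longitude")])
      locs <- merge(stats::aggregate(date ~ seal_year_id, daily, min), locs)
      filtered <- apply_haulout_filter(
        data.frame(seal_year_id = hourly$seal_year_id,
                   timestamp = hourly$timestamp,
                   percent_dry = hourly$percent_dry))
      prepped <- build_daily_series(filtered, locs)
      # re-attach simulated covariates by seal-day
      keyp <- paste(prepped$seal_year_id, prepped$date)
      keyd <- paste(daily$seal_year_id, daily$date)
      m <- match(keyp, keyd)
      for (v in c("doy", "year", "air_temp", "daylength", "sex", "age_class")) {
        prepped[[v]] <- daily[[v]][m]
      }
      daily <- prepped[!is.na(m), , drop = FALSE]
    }
  } else if (!is.null(cfg$daily_series)) {
    daily <- cfg$daily_series
  } else {
    stop("config must provide either 'sim' or 'daily_series'")
  }
  if (!all(all.vars(cfg$formula) %in% names(daily))) {
    daily <- annotate_series(daily, temp_grid = cfg$temp_grid,
                             sic_grid = cfg$sic_grid,
                             melt_early_grid = cfg$melt_early_grid,
                             melt_cont_grid = cfg$melt_cont_grid)
  }
  write_daily_csv(daily, file.path(cfg$out_dir, "daily_series.csv"))

  fit <- emergence_hmm(cfg$formula, daily, nstarts = cfg$nstarts,
                       seed = cfg$seed)
  decoded <- viterbi(fit)
  utils::write.csv(decoded, file.path(cfg$out_dir, "decoded_states.csv"),
                   row.names = FALSE, na = "")
  emergence <- emergence_dates(decoded, daily)
  utils::write.csv(emergence, file.path(cfg$out_dir, "emergence_dates.csv"),
                   row.names = FALSE, na = "")
  summaries <- state_summaries(decoded, daily)

  trends <- NULL
  if (isTRUE(cfg$run_trends) && nrow(emergence) >= 3 &&
      all(c("latitude", "year") %in% names(emergence))) {
    fits <- list(fit_trend(emergence, "latitude"))
    if (length(unique(emergence$year)) > 1) {
      fits <- c(fits, list(fit_trend(emergence, "year")))
    }
    trends <- list(fits = fits,
                   comparison = if (length(fits) > 1)
                     compare_trends(fits, emergence) else NULL)
  }
  loo <- if (isTRUE(cfg$run_loo)) leave_one_out(fit) else NULL

  files <- list.files(cfg$out_dir, full.names = TRUE)
  manifest <- data.frame(artifact = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = cfg$seed, stringsAsFactors = FALSE)
  list(fit = fit, decoded = decoded, emergence = emergence,
       summaries = summaries, trends = trends, loo = loo,
       manifest = manifest, truth = truth, daily_series = daily)
}
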
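#' Linear trend in emergence date
#'
#' Ordinary least squares of emergence day-of-year on a single predictor
#' (latitude or year), with small-sample corrected AIC. AICc uses the
#' usual correction `AIC + 2k(k+1)/(n-k-1)` with `k` counting all
#' estimated parameters including the residual variance.
#'
#' @param emergence emergence table (see [emergence_dates()]) with column
#'   `emergence_doy` and the predictor.
#' @param predictor `"latitude"` or `"year"` (any numeric column name).
#' @return object of class `trend_fit`: the `lm` fit plus `AICc`, `n`,
#'   `predictor`.
#' @export
fit_trend <- function(emergence, predictor = "latitude") {
  stopifnot(predictor %in% names(emergence), nrow(emergence) >= 3)
  x <- emergence[[predictor]]
  if (length(unique(x)) < 2) stop("predictor '", predictor, "' is constant")
  f <- stats::as.formula(paste("emergence_doy ~", predictor))
  fit <- stats::lm(f, data = emergence)
  n <- nrow(emergence)
  k <- attr(stats::logLik(fit), "df")
  if (n - k - 1 <= 0) stop("too few rows for AICc")
  aicc <- stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
  year_mode <- if ("year" %in% names(emergence)) {
    as.integer(names(sort(table(emergence$year), decreasing = TRUE))[1])
  } else NA_integer_
  structure(list(lm = fit, predictor = predictor, n = n, k = k,
                 AIC = stats::AIC(fit), AICc = aicc, year_mode = year_mode,
                 coefficients = summary(fit)$coefficients),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Emergence-date trend: emergence_doy ~", x$predictor, "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("n = %d   AICc = %.2f\n", x$n, x$AICc))
  invisible(x)
}

#' Compare candidate emergence-date trends by AICc
#'
#' Ranks trend fits on identical rows by AICc and reports the Spearman
#' rank correlation between the two predictors as a collinearity
#' diagnostic (latitude and year are typically confounded in multi-year
#' tagging datasets).
#'
#' @param fits list of [fit_trend()] objects fitted to the same table.
#' @param emergence the emergence table (for the collinearity diagnostic);
#'   optional.
#' @return data.frame: `predictor`, `k`, `AICc`, `delta_aicc`, `best`;
#'   when `emergence` is given, the predictor rank correlation is
#'   attached as attribute `"collinearity"`.
#' @export
compare_trends <- function(fits, emergence = NULL) {
  n <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(n)) != 1) stop("fits use differing numbers of rows")
  tab <- data.frame(
    predictor = vapply(fits, function(f) f$predictor, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    stringsAsFactors = FALSE)
  tab$delta_aicc <- tab$AICc - min(tab$AICc)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  if (!is.null(emergence) && length(fits) == 2) {
    attr(tab, "collinearity") <- rank_correlation(
      emergence[[fits[[1]]$predictor]], emergence[[fits[[2]]$predictor]])
  }
  tab
}

#' Predict mean emergence date at a covariate value
#'
#' Point prediction and t-based 95% confidence interval for the
#' conditional mean emergence DOY at `x0`, e.g. the mean emergence date
#' expected at a reference latitude.
#'
#' @param fit a [fit_trend()] object.
#' @param x0 predictor value at which to predict.
#' @param level confidence level (default 0.95).
#' @return list: `doy` (point), `lower`, `upper`, and the corresponding
#'   calendar `date`, `date_lower`, `date_upper` in the fit's modal year.
#' @export
predict_mean <- function(fit, x0, level = 0.95) {
  nd <- stats::setNames(data.frame(x0), fit$predictor)
  pr <- stats::predict(fit$lm, newdata = nd, interval = "confidence",
                       level = level)
  yr <- fit$year_mode
  if (is.na(yr)) yr <- 2015L
  to_date <- function(doy) as.Date(doy - 1, origin = sprintf("%d-01-01", yr))
  list(doy = pr[1, "fit"], lower = pr[1, "lwr"], upper = pr[1, "upr"],
       date = to_date(round(pr[1, "fit"])),
       date_lower = to_date(round(pr[1, "lwr"])),
       date_upper = to_date(round(pr[1, "upr"])))
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank tie handling, via [stats::cor.test()].
#'
#' @param x,y numeric vectors without missing pairs, `n >= 3`.
#' @return list: `rho`, `p_value`, `n`.
#' @export
rank_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  stopifnot(length(x) >= 3)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
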
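#' Zero-one-inflated beta density
#'
#' Density/mass function of the zero-one-inflated beta (ZOIB) distribution
#' used for the daily proportion of time hauled out. The distribution places
#' point masses `p0` at 0 and `p1` at 1, and spreads the remaining
#' probability `1 - p0 - p1` over (0, 1) as a Beta(`shape1`, `shape2`)
#' density. Exact zeros arise on days a seal never left the water; exact
#' ones on days it stayed hauled out around the clock.
#'
#' @param x numeric vector of proportions in \[0, 1\]. `NA` allowed
#'   (returned as `NA`).
#' @param p0 probability mass at 0.
#' @param p1 probability mass at 1. Requires `p0 + p1 <= 1`.
#' @param shape1,shape2 positive beta shape parameters for the interior.
#' @param log logical; return log density/mass?
#' @return numeric vector of density (interior) or mass (endpoints) values.
#' @examples
#' dzoib(c(0, 0.5, 1), p0 = 0.3, p1 = 0.05, shape1 = 2, shape2 = 5)
#' @export
dzoib <- function(x, p0, p1, shape1, shape2, log = FALSE) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1, shape1 > 0, shape2 > 0)
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("'x' must lie in [0, 1]")
  }
  d <- numeric(length(x))
  d[!is.na(x) & x == 0] <- p0
  d[!is.na(x) & x == 1] <- p1
  mid <- !is.na(x) & x > 0 & x < 1
  d[mid] <- (1 - p0 - p1) * stats::dbeta(x[mid], shape1, shape2)
  d[is.na(x)] <- NA_real_
  if (log) base::log(d) else d
}

#' Sample from a zero-one-inflated beta distribution
#'
#' @param n number of draws.
#' @inheritParams dzoib
#' @return numeric vector in \[0, 1\].
#' @export
rzoib <- function(n, p0, p1, shape1, shape2) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1, shape1 > 0, shape2 > 0)
  u <- stats::runif(n)
  out <- numeric(n)
  at0 <- u < p0
  at1 <- u >= p0 & u < p0 + p1
  mid <- !at0 & !at1
  out[at0] <- 0
  out[at1] <- 1
  out[mid] <- stats::rbeta(sum(mid), shape1, shape2)
  out
}

#' Mean and SD of a zero-one-inflated beta distribution
#'
#' Moments of the full mixture (masses plus interior beta), handy for
#' comparing fitted states with reported per-state haul-out proportions.
#'
#' @inheritParams dzoib
#' @return named numeric vector `c(mean = , sd = )`.
#' @export
zoib_moments <- function(p0, p1, shape1, shape2) {
  m_beta <- shape1 / (shape1 + shape2)
  v_beta <- shape1 * shape2 / ((shape1 + shape2)^2 * (shape1 + shape2 + 1))
  pc <- 1 - p0 - p1
  m <- p1 + pc * m_beta
  ex2 <- p1 + pc * (v_beta + m_beta^2)
  c(mean = m, sd = sqrt(max(ex2 - m^2, 0)))
}

#' von Mises density
#'
#' Circular analogue of the normal distribution, used for the daily peak
#' haul-out hour expressed in radians with solar noon at 0. Density
#' `exp(kappa * cos(theta - mu)) / (2 * pi * I0(kappa))`, evaluated with the
#' exponentially scaled Bessel function so large concentrations do not
#' overflow. `kappa = 0` gives the circular uniform density `1/(2*pi)`.
#'
#' @param theta angle(s) in radians; any real value (period `2*pi`).
#' @param mu mean direction in radians.
#' @param kappa concentration, `>= 0`.
#' @param log logical; return log density?
#' @return numeric vector of densities.
#' @export
dvonmises <- function(theta, mu, kappa, log = FALSE) {
  stopifnot(kappa >= 0)
  ld <- kappa * (cos(theta - mu) - 1) -
    base::log(2 * pi) - base::log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher wrapped-Cauchy rejection sampler; exact for all `kappa`,
#' uniform on the circle when `kappa = 0`.
#'
#' @param n number of draws.
#' @inheritParams dvonmises
#' @return angles in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (base::log(cc / u2) + 1 - cc >= 0)
    nf <- sum(ok)
    if (nf > 0) {
      u3 <- stats::runif(nf)
      theta <- sign(u3 - 0.5) * acos(f[ok]) + mu
      out[(got + 1L):(got + nf)] <- theta
      got <- got + nf
    }
  }
  wrap_angle(out)
}

#' Wrap angles to \[-pi, pi)
#'
#' @param theta angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(theta) {
  ((theta + pi) %% (2 * pi)) - pi
}

#' Circular mean direction
#'
#' Mean direction of angles, optionally weighted. Returns `NA` when the
#' resultant length is (numerically) zero, i.e. the direction is undefined.
#'
#' @param theta angles in radians.
#' @param w optional non-negative weights.
#' @param na.rm drop missing angles first?
#' @return mean direction in `[-pi, pi)`, or `NA`.
#' @export
circular_mean <- function(theta, w = NULL, na.rm = FALSE) {
  if (na.rm) {
    keep <- !is.na(theta) & if (is.null(w)) TRUE else !is.na(w)
    theta <- theta[keep]
    if (!is.null(w)) w <- w[keep]
  }
  if (length(theta) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w * sin(theta))
  c_ <- sum(w * cos(theta))
  if (sqrt(s^2 + c_^2) < 1e-10 * max(sum(abs(w)), 1)) return(NA_real_)
  wrap_angle(atan2(s, c_))
}

#' Convert between peak-hour radians and solar clock hours
#'
#' The package stores peak haul-out hour as radians in `[-pi, pi)` with
#' solar noon (12:00) at 0. These helpers convert to and from solar clock
#' hours in `[0, 24)`.
#'
#' @param theta radians in `[-pi, pi)`.
#' @param hour solar clock hour in `[0, 24)`.
#' @return the converted value.
#' @export
radians_to_solar_hour <- function(theta) {
  (theta * 24 / (2 * pi) + 12) %% 24
}

#' @rdname radians_to_solar_hour
#' @export
solar_hour_to_radians <- function(hour) {
  wrap_angle((hour - 12) * 2 * pi / 24)
}
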
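# Angle arithmetic, the von Mises density, and the kappa <-> circular-SD
# conversion underlying the "precision" measure.
#
# Internal unit convention: angles are radians; every user-facing input and
# output (targets, responses, SDs) is in degrees. Precision is 1/SD with SD
# in degrees, so typical values sit in the 0.04-0.10 range for human
# continuous-report data (SD ~ 10-25 deg).

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap a signed angle into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles mapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps the lower boundary to -pi; the convention here is (-pi, pi]
  w[w <= -pi] <- pi
  w
}

#' Signed recall error between a response and its target
#'
#' Computes the minimal signed angular difference `response - target`, the
#' datum of a continuous-reproduction trial. Inputs are degrees on any
#' range; the result is radians in (-pi, pi], positive when the response is
#' counter-clockwise of the target along the shorter arc.
#'
#' @param target numeric vector, target feature in degrees.
#' @param response numeric vector, reproduced feature in degrees.
#' @return numeric vector of signed errors in radians, in (-pi, pi].
#' @examples
#' wrap_error(350, 10)   # +20 deg wrap-around -> 0.349 rad
#' wrap_error(0, 270)    # shorter arc is -90 deg -> -pi/2
#' @export
wrap_error <- function(target, response) {
  if (!is.numeric(target) || !is.numeric(response) ||
      any(!is.finite(target)) || any(!is.finite(response))) {
    stop("wrap_error: target and response must be finite numerics")
  }
  wrap_angle((response - target) * DEG2RAD)
}

#' Von Mises probability density
#'
#' Density of the von Mises distribution with mean direction `mu` and
#' concentration `kappa`, evaluated at `x` (all radians). At `kappa = 0`
#' this is the circular uniform density 1/(2*pi).
#'
#' @param x numeric vector, angles in radians.
#' @param mu mean direction in radians (default 0: error space).
#' @param kappa concentration parameter, >= 0.
#' @return density values.
#' @export
vm_pdf <- function(x, mu = 0, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa < 0) {
    stop("vm_pdf: kappa must be a single finite value >= 0")
  }
  # exponentially-scaled Bessel keeps this finite for large kappa
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Log von Mises density (internal, vectorised over x)
#' @keywords internal
vm_logpdf <- function(x, kappa) {
  kappa * (cos(x) - 1) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
}

#' Mean resultant length of a von Mises distribution
#'
#' R(kappa) = I1(kappa) / I0(kappa), the first trigonometric moment.
#' @param kappa concentration, >= 0.
#' @keywords internal
vm_resultant <- function(kappa) {
  if (kappa > 1e5) {
    # asymptotic expansion; scaled Bessel underflows for very large kappa
    return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3))
  }
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Convert von Mises concentration to circular standard deviation
#'
#' Uses the standard definition SD = sqrt(-2 log R) with mean resultant
#' length R = I1(kappa)/I0(kappa), returned in degrees. This is the
#' conversion conventional in mixture-model analyses of continuous report;
#' the reciprocal 1/SD (in 1/degrees) is the "precision" measure.
#'
#' Strictly decreasing in kappa; kappa = 0 gives Inf (uniform responses
#' carry no precision).
#'
#' @param kappa concentration parameter, >= 0 (vectorised).
#' @return circular SD in degrees.
#' @export
kappa_to_sd <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("kappa_to_sd: kappa must be finite and >= 0")
  }
  r <- vapply(kappa, vm_resultant, numeric(1))
  sd_rad <- ifelse(r <= 0, Inf, sqrt(-2 * log(r)))
  sd_rad * RAD2DEG
}

#' Convert a circular standard deviation (degrees) to concentration
#'
#' Numerical inverse of [kappa_to_sd()], found by monotone root bracketing
#' in log(kappa). Round-trips to better than 1e-6 degrees over the range
#' relevant to behavioural data (roughly 1 to 120 degrees).
#'
#' @param sd_deg circular SD in degrees, > 0 (vectorised).
#' @return concentration kappa.
#' @export
sd_to_kappa <- function(sd_deg) {
  if (!is.numeric(sd_deg) || any(!is.finite(sd_deg)) || any(sd_deg <= 0)) {
    stop("sd_to_kappa: sd must be finite and > 0")
  }
  one <- function(s) {
    f <- function(lk) kappa_to_sd(exp(lk)) - s
    lo <- -34; hi <- 34  # kappa in [~2e-15, ~6e14]
    if (f(lo) < 0) return(exp(lo))  # sd beyond the uniform limit: kappa ~ 0
    if (f(hi) > 0) return(exp(hi))
    exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }
  vapply(sd_deg, one, numeric(1))
}

#' Precision (1/SD in degrees) from concentration
#' @param kappa concentration parameter, >= 0.
#' @return precision in 1/degrees (0 when kappa = 0).
#' @export
kappa_to_precision <- function(kappa) {
  1 / kappa_to_sd(kappa)
}

#' Draw from a von Mises distribution (Best-Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration, >= 0; kappa = 0 samples uniformly.
#' @return angles in (-pi, pi].
#' @keywords internal
rvonmises <- function(n, mu = 0, kappa) {
  if (kappa < 0) stop("rvonmises: kappa must be >= 0")
  if (kappa < 1e-8) {
    return(wrap_angle(stats::runif(n, -pi, pi)))
  }
  # Best & Fisher (1979) wrapped-Cauchy envelope rejection
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(ok)
    if (nk > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nk)] <- theta
      got <- got + nk
    }
  }
  wrap_angle(out + mu)
}
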
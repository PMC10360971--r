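# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (series Bessel instead of besselI, direct
# quadrature instead of the closed-form conversions, per-trial loops
# instead of vectorised likelihoods).

# modified Bessel function of the first kind by direct series summation
bessel_series <- function(x, nu, terms = 60L) {
  k <- 0:terms
  sum((x / 2)^(2 * k + nu) / (factorial(k) * gamma(k + nu + 1)))
}

# mean resultant length of a von Mises by quadrature (no Bessel at all)
vm_rbar_quad <- function(kappa) {
  num <- stats::integrate(function(x) cos(x) * exp(kappa * (cos(x) - 1)),
                          -pi, pi, rel.tol = 1e-12)$value
  den <- stats::integrate(function(x) exp(kappa * (cos(x) - 1)),
                          -pi, pi, rel.tol = 1e-12)$value
  num / den
}

# circular SD (degrees) via the quadrature resultant
sd_quad_deg <- function(kappa) sqrt(-2 * log(vm_rbar_quad(kappa))) * 180 / pi

# per-trial brute-force mixture log-likelihood with series Bessel
smm_loglik_brute <- function(errors, g, kappa) {
  i0 <- bessel_series(kappa, 0)
  total <- 0
  for (x in errors) {
    total <- total +
      log((1 - g) * exp(kappa * cos(x)) / (2 * pi * i0) + g / (2 * pi))
  }
  total
}

# Gunel-Dickey Poisson-sampling BF by numerical integration of the
# marginal likelihoods under the generative priors (2x2 only):
# H1: independent Gamma(a, b) cell rates, b = 4a/n;
# H0: total ~ Gamma(4a - 1, b), row and column splits ~ Beta(2a-1, 2a-1).
gd_poisson_numeric <- function(y, a = 1) {
  n <- sum(y)
  b <- 4 * a / n
  m1 <- prod(vapply(c(y), function(yy) {
    stats::integrate(function(l) stats::dpois(yy, l) * stats::dgamma(l, a, rate = b),
                     0, Inf, rel.tol = 1e-11)$value
  }, numeric(1)))
  sh <- 4 * a - 1
  ab <- 2 * a - 1
  yr <- rowSums(y); yc <- colSums(y)
  mLam <- stats::integrate(function(l) exp(-l) * l^n * stats::dgamma(l, sh, rate = b),
                           0, Inf, rel.tol = 1e-11)$value
  mp <- stats::integrate(function(p) p^yr[1] * (1 - p)^yr[2] * stats::dbeta(p, ab, ab),
                         0, 1, rel.tol = 1e-11)$value
  mq <- stats::integrate(function(q) q^yc[1] * (1 - q)^yc[2] * stats::dbeta(q, ab, ab),
                         0, 1, rel.tol = 1e-11)$value
  m1 / (mLam * mp * mq / prod(factorial(c(y))))
}

# independent-multinomial (rows fixed) BF by numerical integration:
# H1: within-row split ~ Beta(a, a) per row; H0: common split ~ Beta(2a-1, 2a-1)
gd_indepmulti_numeric <- function(y, a = 1) {
  yr <- rowSums(y); yc <- colSums(y)
  m1 <- prod(vapply(1:2, function(i) {
    stats::integrate(function(p) p^y[i, 1] * (1 - p)^y[i, 2] * stats::dbeta(p, a, a),
                     0, 1, rel.tol = 1e-11)$value
  }, numeric(1)))
  ab <- 2 * a - 1
  m0 <- stats::integrate(function(q) q^yc[1] * (1 - q)^yc[2] * stats::dbeta(q, ab, ab),
                         0, 1, rel.tol = 1e-11)$value
  m1 / m0
}

# small fast study configuration for pipeline tests
tiny_study_config <- function(seed = 1, scenario = "null", ...) {
  study_sim_config(n_experimental = 6, n_control = 6,
                   phases = c("pre", "post"),
                   tasks = "orientation_reproduction",
                   trials_per_cell = 60, practice_trials = 0,
                   scenario = scenario, seed = seed, ...)
}
tiny_analysis_config <- function(...) {
  analysis_config(expected_test_trials = 60L, ...)
}
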
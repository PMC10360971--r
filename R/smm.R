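# The standard mixture model (SMM) of continuous-report recall errors:
# a von Mises component centred on the target (items in memory, recalled
# with limited precision) plus a circular-uniform component (random
# guesses). The guess probability g gives the quantity measure
# (Pm = 1 - g, capacity K = Pm * N) and the concentration kappa gives the
# quality measure (precision = 1/SD, SD in degrees).

#' SMM log-likelihood
#'
#' Sum over trials of log[(1 - g) * vm(x; 0, kappa) + g / (2*pi)], with
#' errors `x` in radians (target-relative, so the von Mises mean is 0).
#'
#' @param errors numeric vector of signed recall errors in radians.
#' @param g guess probability in [0, 1].
#' @param kappa von Mises concentration, >= 0.
#' @return scalar log-likelihood.
#' @export
smm_loglik <- function(errors, g, kappa) {
  if (length(errors) < 1L) stop("smm_loglik: needs at least one error")
  if (!is.finite(g) || g < 0 || g > 1) stop("smm_loglik: g must be in [0, 1]")
  if (!is.finite(kappa) || kappa < 0) stop("smm_loglik: kappa must be >= 0")
  dens <- (1 - g) * vm_pdf(errors, 0, kappa) + g / (2 * pi)
  sum(log(dens))
}

# negative log-likelihood and gradient in unconstrained space
# theta = (logit g, log kappa)
.smm_nll <- function(theta, errors) {
  g <- stats::plogis(theta[1L])
  kappa <- exp(theta[2L])
  -smm_loglik(errors, g, kappa)
}

.smm_nll_grad <- function(theta, errors) {
  g <- stats::plogis(theta[1L])
  kappa <- exp(theta[2L])
  f <- vm_pdf(errors, 0, kappa)
  u <- (1 - g) * f + g / (2 * pi)
  # d nll / d g, then chain through logit
  dg <- sum((f - 1 / (2 * pi)) / u) * g * (1 - g)
  rbar <- vm_resultant(kappa)
  dk <- -sum((1 - g) * f * (cos(errors) - rbar) / u) * kappa
  c(dg, dk)
}

#' Fit the standard mixture model by maximum likelihood
#'
#' Maximises the SMM likelihood over (g, kappa) by quasi-Newton search in
#' (logit g, log kappa) space with analytic gradients, from a fixed lattice
#' of 8 starting points (g in {.1, .5, .9} crossed with kappa in
#' {2, 8, 32}, centre point dropped). The multi-start guards against the
#' ridge along which a high guess rate trades off against a low
#' concentration. The procedure is deterministic.
#'
#' @param errors signed recall errors in radians (use [wrap_error()] to
#'   build them from degrees).
#' @param set_size number of items in the memory array; used to derive
#'   capacity K = (1 - g) * set_size. `NA` leaves capacity unset.
#' @param min_trials minimum number of trials required (default 30); fewer
#'   trials give unstable estimates and raise an error.
#' @param g_bounds,kappa_bounds box constraints on the parameters.
#' @return an object of class `smm_fit`: a list with elements `g`, `kappa`,
#'   `pm`, `capacity_k`, `sd_deg`, `precision`, `loglik`, `n_trials`,
#'   `set_size`, `converged`, `boundary`, `n_starts`.
#' @export
fit_smm <- function(errors, set_size = NA,
                    min_trials = 30L,
                    g_bounds = c(1e-6, 1 - 1e-6),
                    kappa_bounds = c(1e-3, 500)) {
  errors <- errors[is.finite(errors)]
  n <- length(errors)
  if (n < min_trials) {
    stop(sprintf("fit_smm: %d trials < min_trials = %d (insufficient data)",
                 n, min_trials))
  }
  starts <- expand.grid(g = c(0.1, 0.5, 0.9), kappa = c(2, 8, 32))
  starts <- starts[!(starts$g == 0.5 & starts$kappa == 8), , drop = FALSE]
  lower <- c(stats::qlogis(g_bounds[1L]), log(kappa_bounds[1L]))
  upper <- c(stats::qlogis(g_bounds[2L]), log(kappa_bounds[2L]))

  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    th0 <- c(stats::qlogis(starts$g[i]), log(starts$kappa[i]))
    fit <- tryCatch(
      stats::optim(th0, .smm_nll, gr = .smm_nll_grad, errors = errors,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("fit_smm: optimisation failed from every start")

  g <- stats::plogis(best$par[1L])
  kappa <- exp(best$par[2L])
  boundary <- kappa >= kappa_bounds[2L] * 0.999 ||
    kappa <= kappa_bounds[1L] * 1.001 ||
    g <= g_bounds[1L] * 1.001 || g >= 1 - (1 - g_bounds[2L]) * 1.001
  if (boundary) {
    warning("fit_smm: estimate at parameter boundary; fit flagged")
  }
  sd_deg <- kappa_to_sd(kappa)
  structure(list(
    g = g, kappa = kappa,
    pm = 1 - g,
    capacity_k = if (is.na(set_size)) NA_real_ else (1 - g) * set_size,
    sd_deg = sd_deg,
    precision = 1 / sd_deg,
    loglik = -best$value,
    n_trials = n,
    set_size = set_size,
    converged = any_conv,
    boundary = boundary,
    n_starts = nrow(starts)
  ), class = "smm_fit")
}

#' @export
print.smm_fit <- function(x, ...) {
  cat("Standard mixture model fit (", x$n_trials, " trials)\n", sep = "")
  cat(sprintf("  g = %.3f  (Pm = %.3f)\n", x$g, x$pm))
  cat(sprintf("  kappa = %.2f  (SD = %.1f deg, precision = %.4f)\n",
              x$kappa, x$sd_deg, x$precision))
  if (!is.na(x$capacity_k)) {
    cat(sprintf("  capacity K = %.2f of set size %d\n",
                x$capacity_k, as.integer(x$set_size)))
  }
  cat(sprintf("  logLik = %.2f, converged = %s%s\n", x$loglik, x$converged,
              if (isTRUE(x$boundary)) " (boundary)" else ""))
  invisible(x)
}

#' Capacity from the guess rate
#'
#' K = (1 - g) * N: the number of items in memory implied by the guess
#' probability at a given set size. Ranges from 0 (pure guessing) to the
#' set size (no guessing).
#'
#' @param g guess probability in [0, 1].
#' @param set_size number of items, >= 1.
#' @return capacity in items.
#' @export
capacity_from_g <- function(g, set_size) {
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1)) {
    stop("capacity_from_g: g must be in [0, 1]")
  }
  if (any(!is.finite(set_size)) || any(set_size < 1)) {
    stop("capacity_from_g: set_size must be >= 1")
  }
  (1 - g) * set_size
}
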
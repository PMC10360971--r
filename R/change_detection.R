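# Whole-display change-detection capacity: Pashler's k.

#' Hit / false-alarm summary from response counts
#'
#' @param hits,misses counts on change trials.
#' @param false_alarms,correct_rejections counts on match trials.
#' @param set_size display set size N.
#' @param correction apply the log-linear 1/(2n) adjustment (add 0.5 to the
#'   numerator count and 1 to the denominator of each rate). Off by
#'   default: rates are reported raw.
#' @return a list of class `detection_summary` with `H`, `FA`, `set_size`,
#'   `n_change_trials`, `n_match_trials`.
#' @export
rates_from_counts <- function(hits, misses, false_alarms, correct_rejections,
                              set_size = NA, correction = FALSE) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("rates_from_counts: counts must be nonnegative")
  }
  nc <- hits + misses
  nm <- false_alarms + correct_rejections
  if (nc < 1 || nm < 1) stop("rates_from_counts: empty trial condition")
  if (correction) {
    H <- (hits + 0.5) / (nc + 1)
    FA <- (false_alarms + 0.5) / (nm + 1)
  } else {
    H <- hits / nc
    FA <- false_alarms / nm
  }
  structure(list(H = H, FA = FA, set_size = set_size,
                 n_change_trials = nc, n_match_trials = nm),
            class = "detection_summary")
}

#' Pashler's k for whole-display change detection
#'
#' k = (H - FA) / (1 - FA) * N, where H and FA are the hit and
#' false-alarm rates and N the display set size. Under the whole-display
#' guessing model, an observer holding k of N items detects a change with
#' probability k/N and otherwise guesses, so this estimator is unbiased in
#' expectation for any guess rate.
#'
#' @param summary a `detection_summary` (see [rates_from_counts()]), or a
#'   list with fields `H`, `FA`, `set_size`.
#' @param clamp clamp the estimate to [0, N] (default); the raw value is
#'   retained in the result either way.
#' @return list with `k` (headline, clamped when `clamp`), `k_raw`, `H`,
#'   `FA`, `set_size`.
#' @export
pashler_k <- function(summary, clamp = TRUE) {
  H <- summary$H; FA <- summary$FA; N <- summary$set_size
  if (is.na(N) || N < 1) stop("pashler_k: set_size required")
  if (any(c(H, FA) < 0) || any(c(H, FA) > 1)) {
    stop("pashler_k: rates must be in [0, 1]")
  }
  if (FA >= 1) stop("pashler_k: FA = 1 leaves k undefined")
  k_raw <- (H - FA) / (1 - FA) * N
  k <- if (clamp) min(max(k_raw, 0), N) else k_raw
  list(k = k, k_raw = k_raw, H = H, FA = FA, set_size = N)
}
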
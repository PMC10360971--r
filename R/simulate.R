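# Trial-level simulator for a two-group pre/post visual working memory
# training study: continuous-reproduction tasks generated from the
# standard mixture model, whole-display change detection from the
# guessing model underlying Pashler's k, and visual search with Bernoulli
# accuracy and log-normal response times.
#
# The default configuration mirrors the design the analysis pipeline
# expects: an experimental group (n = 30) training orientation
# reproduction and an active control group (n = 34) training visual
# search; pre- and post-test sessions with 120 test trials (plus 20
# flagged practice trials) per task at set size 4 (16 for search); and
# four training sessions of 360 trials each, 120 per set size (2, 4, 6
# reproduction; 8, 16, 24 search).

TASKS_REPRO <- c("orientation_reproduction", "shape_reproduction")
PHASES_ALL <- c("pre", "s1", "s2", "s3", "s4", "post")

#' Draw recall errors from the standard mixture model
#'
#' With probability `g` a trial is a uniform guess on (-pi, pi]; otherwise
#' the error is von Mises(0, kappa).
#'
#' @param n number of trials.
#' @param g guess probability in [0, 1].
#' @param kappa von Mises concentration, >= 0.
#' @param seed optional integer seed for reproducibility.
#' @return signed errors in radians in (-pi, pi].
#' @export
simulate_errors <- function(n, g, kappa, seed = NULL) {
  if (!is.finite(g) || g < 0 || g > 1) stop("simulate_errors: g must be in [0, 1]")
  if (!is.finite(kappa) || kappa < 0) stop("simulate_errors: kappa must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  guess <- stats::runif(n) < g
  err <- rvonmises(n, 0, kappa)
  err[guess] <- wrap_angle(stats::runif(sum(guess), -pi, pi))
  err
}

#' Simulate whole-display change-detection trials
#'
#' Generative counterpart of Pashler's k: on a change trial the changed
#' item is one of `k_true` items held in memory with probability
#' `k_true / N`, in which case the observer responds "change"; otherwise
#' (and on every match trial, where no change can be detected) the
#' observer guesses "change" with rate `u`. Under this model
#' E[H] = k/N + (1 - k/N) u and E[FA] = u, so the Pashler estimator
#' recovers `k_true` in expectation for any guess rate. Change and match
#' trials are balanced.
#'
#' @param k_true true capacity, 0 <= k_true <= N.
#' @param N display set size.
#' @param n_trials total number of trials (half change, half match).
#' @param u guess rate for responding "change" when nothing was detected.
#' @param seed optional integer seed.
#' @return data.frame with `change_trial` (logical) and `response_key`
#'   ("change"/"match").
#' @export
simulate_change_detection <- function(k_true, N, n_trials, u = 0.5, seed = NULL) {
  if (!is.finite(k_true) || k_true < 0 || k_true > N) {
    stop("simulate_change_detection: k_true must be in [0, N]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_change <- floor(n_trials / 2)
  change <- sample(rep(c(TRUE, FALSE), c(n_change, n_trials - n_change)))
  detect <- change & (stats::runif(n_trials) < k_true / N)
  say_change <- detect | (!detect & stats::runif(n_trials) < u)
  data.frame(change_trial = change,
             response_key = ifelse(say_change, "change", "match"),
             stringsAsFactors = FALSE)
}

#' Simulate visual search trials
#'
#' Bernoulli accuracy and log-normal response times (moment-matched to
#' `rt_mean`, `rt_sd`). Responses slower than `rt_cap` (the response
#' deadline, default 5000 ms) are omissions, as are a further
#' `omission_rate` of trials; omitted trials carry no response.
#'
#' @param n_trials number of trials.
#' @param accuracy probability of a correct response.
#' @param rt_mean,rt_sd response-time mean and SD in ms.
#' @param omission_rate base rate of non-responses.
#' @param rt_cap response deadline in ms.
#' @param seed optional integer seed.
#' @return data.frame with `change_trial` (target present), `response_key`,
#'   `correct`, `rt_ms`, `omitted`.
#' @export
simulate_visual_search <- function(n_trials, accuracy, rt_mean, rt_sd,
                                   omission_rate = 0.02, rt_cap = 5000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_present <- floor(n_trials / 2)
  present <- sample(rep(c(TRUE, FALSE), c(n_present, n_trials - n_present)))
  sdlog <- sqrt(log(1 + (rt_sd / rt_mean)^2))
  meanlog <- log(rt_mean) - sdlog^2 / 2
  rt <- stats::rlnorm(n_trials, meanlog, sdlog)
  omitted <- rt > rt_cap | stats::runif(n_trials) < omission_rate
  rt[omitted] <- NA_real_
  correct <- stats::runif(n_trials) < accuracy
  # target present -> "change" key; absent -> "match" key
  truth <- ifelse(present, "change", "match")
  other <- ifelse(present, "match", "change")
  key <- ifelse(correct, truth, other)
  key[omitted] <- NA_character_
  data.frame(change_trial = present, response_key = key,
             correct = ifelse(omitted, NA, correct), rt_ms = rt,
             omitted = omitted, stringsAsFactors = FALSE)
}

# default (g, SD in degrees) per group x phase x task x set size; values
# chosen to sit in the range typical of healthy young adults on these
# tasks (capacity ~2-3 items at set size 4, SD ~ 12-21 deg)
.default_gk <- function(scenario = c("null", "quality_gain"),
                        quality_gain_sd_ratio = 0.8) {
  scenario <- match.arg(scenario)
  rows <- list()
  add <- function(group, phase, task, set_size, g, sd_deg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, phase = phase, task = task, set_size = set_size,
      g = g, sd_deg = sd_deg, stringsAsFactors = FALSE)
  }
  for (grp in c("experimental", "control")) {
    for (ph in c("pre", "post")) {
      add(grp, ph, "orientation_reproduction", 4, 0.39, 16.7)
      add(grp, ph, "shape_reproduction", 4, 0.44, 21.0)
    }
  }
  # training: reproduction cells exist for the experimental group only
  train_g <- c(`2` = 0.06, `4` = 0.30, `6` = 0.48)
  train_sd <- c(`2` = 11.8, `4` = 15.4, `6` = 16.7)
  for (ph in c("s1", "s2", "s3", "s4")) {
    for (ss in c(2, 4, 6)) {
      add("experimental", ph, "orientation_reproduction", ss,
          train_g[[as.character(ss)]], train_sd[[as.character(ss)]])
    }
  }
  gk <- do.call(rbind, rows)
  if (scenario == "quality_gain") {
    sel <- gk$group == "experimental" & gk$phase == "post" &
      gk$task == "orientation_reproduction"
    gk$sd_deg[sel] <- gk$sd_deg[sel] * quality_gain_sd_ratio
  }
  gk
}

#' Build a study-simulation configuration
#'
#' Returns the full configuration consumed by [simulate_study()]. The
#' defaults state the emulated design: group sizes 30 (experimental) and
#' 34 (control), 120 test trials per task at pre/post (set size 4; 16 for
#' search) plus 20 practice trials, and four training sessions of 360
#' trials (120 per set size: 2/4/6 reproduction, 8/16/24 search).
#'
#' @param n_experimental,n_control group sizes.
#' @param scenario `"null"` (no parameter changes from pre to post) or
#'   `"quality_gain"` (the experimental group's post-test reproduction SD
#'   shrinks by `quality_gain_sd_ratio`, guess rate unchanged: a pure
#'   quality improvement with no quantity change).
#' @param quality_gain_sd_ratio post/pre SD ratio under `"quality_gain"`.
#' @param gk optional replacement for the per-cell (g, SD) table; a
#'   data.frame with columns group, phase, task, set_size, g, sd_deg.
#' @param phases phases to simulate (subset of pre, s1..s4, post).
#' @param tasks tasks to simulate at pre/post.
#' @param trials_per_cell test trials per cell (default 120).
#' @param practice_trials flagged practice trials per task at pre/post.
#' @param detection_k_true,detection_u change-detection generative
#'   parameters (true capacity; guess rate).
#' @param search_accuracy,search_rt_mean,search_rt_sd named-by-set-size
#'   vectors of visual-search parameters.
#' @param search_omission_rate base omission rate for search.
#' @param seed integer seed.
#' @return a list of class `study_sim_config`.
#' @export
study_sim_config <- function(n_experimental = 30, n_control = 34,
                             scenario = c("null", "quality_gain"),
                             quality_gain_sd_ratio = 0.8,
                             gk = NULL,
                             phases = PHASES_ALL,
                             tasks = c("orientation_reproduction",
                                       "shape_reproduction",
                                       "change_detection", "visual_search"),
                             trials_per_cell = 120,
                             practice_trials = 20,
                             detection_k_true = 2, detection_u = 0.5,
                             search_accuracy = c(`8` = 0.92, `16` = 0.85,
                                                 `24` = 0.75),
                             search_rt_mean = c(`8` = 2000, `16` = 2800,
                                                `24` = 3150),
                             search_rt_sd = c(`8` = 400, `16` = 430,
                                              `24` = 470),
                             search_omission_rate = 0.02,
                             seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(gk)) gk <- .default_gk(scenario, quality_gain_sd_ratio)
  phases <- match.arg(phases, PHASES_ALL, several.ok = TRUE)
  cfg <- list(n_experimental = n_experimental, n_control = n_control,
              scenario = scenario, gk = gk, phases = phases, tasks = tasks,
              trials_per_cell = trials_per_cell,
              practice_trials = practice_trials,
              detection_k_true = detection_k_true, detection_u = detection_u,
              search_accuracy = search_accuracy,
              search_rt_mean = search_rt_mean, search_rt_sd = search_rt_sd,
              search_omission_rate = search_omission_rate,
              test_set_size = 4, test_search_set_size = 16,
              training_set_sizes = c(2, 4, 6),
              training_search_set_sizes = c(8, 16, 24),
              seed = seed)
  class(cfg) <- "study_sim_config"
  cfg
}

.gk_lookup <- function(gk, group, phase, task, set_size) {
  i <- which(gk$group == group & gk$phase == phase & gk$task == task &
               gk$set_size == set_size)
  if (length(i) != 1L) {
    stop(sprintf("simulate_study: missing (g, SD) cell for %s/%s/%s/N=%s",
                 group, phase, task, set_size))
  }
  list(g = gk$g[i], kappa = sd_to_kappa(gk$sd_deg[i]))
}

.repro_rows <- function(n, id, group, phase, task, set_size, g, kappa,
                        practice = FALSE) {
  target <- stats::runif(n, 0, 360)
  err_deg <- simulate_errors(n, g, kappa) * RAD2DEG
  data.frame(
    participant_id = id, group = group, phase = phase, task = task,
    set_size = set_size, practice = practice,
    target_deg = target, response_deg = (target + err_deg) %% 360,
    change_trial = NA, response_key = NA_character_,
    rt_ms = round(stats::rlnorm(n, log(1500), 0.3), 1), omitted = FALSE,
    stringsAsFactors = FALSE)
}

.detect_rows <- function(n, id, group, phase, set_size, k_true, u,
                         practice = FALSE) {
  d <- simulate_change_detection(k_true, set_size, n, u)
  data.frame(
    participant_id = id, group = group, phase = phase,
    task = "change_detection", set_size = set_size, practice = practice,
    target_deg = NA_real_, response_deg = NA_real_,
    change_trial = d$change_trial, response_key = d$response_key,
    rt_ms = round(stats::rlnorm(n, log(900), 0.3), 1), omitted = FALSE,
    stringsAsFactors = FALSE)
}

.search_rows <- function(n, id, group, phase, set_size, cfg,
                         practice = FALSE) {
  ss <- as.character(set_size)
  d <- simulate_visual_search(n, cfg$search_accuracy[[ss]],
                              cfg$search_rt_mean[[ss]], cfg$search_rt_sd[[ss]],
                              cfg$search_omission_rate)
  data.frame(
    participant_id = id, group = group, phase = phase,
    task = "visual_search", set_size = set_size, practice = practice,
    target_deg = NA_real_, response_deg = NA_real_,
    change_trial = d$change_trial, response_key = d$response_key,
    rt_ms = round(d$rt_ms, 1), omitted = d$omitted,
    stringsAsFactors = FALSE)
}

#' Simulate a complete two-group training study
#'
#' Generates the full trial table for the design stated in the
#' configuration. Group and phase effects enter only through the per-cell
#' (g, SD) table (reproduction), the detection parameters, and the search
#' parameters; everything else is design bookkeeping. Row counts match the
#' design exactly: 120 test rows per participant, task and test phase
#' (plus flagged practice rows), and 360 training rows per participant and
#' session.
#'
#' @param config a `study_sim_config` (see [study_sim_config()]).
#' @return data.frame of trials, one row per trial.
#' @export
simulate_study <- function(config = study_sim_config()) {
  stopifnot(inherits(config, "study_sim_config"))
  set.seed(config$seed)
  # per-set-size search params must cover the test display too
  if ("visual_search" %in% config$tasks) {
    ss <- as.character(config$test_search_set_size)
    if (!ss %in% names(config$search_accuracy)) {
      config$search_accuracy[[ss]] <- 0.78
      config$search_rt_mean[[ss]] <- 3000
      config$search_rt_sd[[ss]] <- 500
    }
  }
  ids <- c(sprintf("E%02d", seq_len(config$n_experimental)),
           sprintf("C%02d", seq_len(config$n_control)))
  groups <- rep(c("experimental", "control"),
                c(config$n_experimental, config$n_control))
  out <- vector("list", 0L)
  n_test <- config$trials_per_cell
  n_prac <- config$practice_trials
  for (p in seq_along(ids)) {
    id <- ids[p]; grp <- groups[p]
    for (phase in config$phases) {
      if (phase %in% c("pre", "post")) {
        for (task in config$tasks) {
          if (task %in% TASKS_REPRO) {
            par <- .gk_lookup(config$gk, grp, phase, task,
                              config$test_set_size)
            if (n_prac > 0) {
              out[[length(out) + 1L]] <- .repro_rows(
                n_prac, id, grp, phase, task, config$test_set_size,
                par$g, par$kappa, practice = TRUE)
            }
            out[[length(out) + 1L]] <- .repro_rows(
              n_test, id, grp, phase, task, config$test_set_size,
              par$g, par$kappa)
          } else if (task == "change_detection") {
            if (n_prac > 0) {
              out[[length(out) + 1L]] <- .detect_rows(
                n_prac, id, grp, phase, config$test_set_size,
                config$detection_k_true, config$detection_u, practice = TRUE)
            }
            out[[length(out) + 1L]] <- .detect_rows(
              n_test, id, grp, phase, config$test_set_size,
              config$detection_k_true, config$detection_u)
          } else if (task == "visual_search") {
            if (n_prac > 0) {
              out[[length(out) + 1L]] <- .search_rows(
                n_prac, id, grp, phase, config$test_search_set_size,
                config, practice = TRUE)
            }
            out[[length(out) + 1L]] <- .search_rows(
              n_test, id, grp, phase, config$test_search_set_size, config)
          }
        }
      } else {
        # training session: task depends on group
        if (grp == "experimental") {
          for (ss in config$training_set_sizes) {
            par <- .gk_lookup(config$gk, grp, phase,
                              "orientation_reproduction", ss)
            out[[length(out) + 1L]] <- .repro_rows(
              n_test, id, grp, phase, "orientation_reproduction", ss,
              par$g, par$kappa)
          }
        } else {
          for (ss in config$training_search_set_sizes) {
            out[[length(out) + 1L]] <- .search_rows(
              n_test, id, grp, phase, ss, config)
          }
        }
      }
    }
  }
  do.call(rbind, out)
}
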
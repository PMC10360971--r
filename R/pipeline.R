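# End-to-end orchestration: validate the canonical trial table, apply
# participant exclusions, fit one estimate per participant x phase x
# set-size cell, and run the full inference layer (baseline comparisons,
# training ANOVAs, pre/post mixed ANOVAs, robust follow-ups, response-
# density comparisons), emitting a machine-readable report.

TRIAL_COLUMNS <- c("participant_id", "group", "phase", "task", "set_size",
                   "practice", "target_deg", "response_deg", "change_trial",
                   "response_key", "rt_ms", "omitted")

#' Validate a trial table against the canonical schema
#'
#' @param trials data.frame of trials.
#' @return invisibly, the validated table; errors describe every violation.
#' @export
validate_trials <- function(trials) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss)) {
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  }
  probs <- character(0)
  repro <- trials$task %in% TASKS_REPRO & !trials$omitted
  deg <- c(trials$target_deg[repro], trials$response_deg[repro])
  if (any(!is.finite(deg)) || any(deg < 0 | deg >= 360)) {
    probs <- c(probs, "reproduction targets/responses must be degrees in [0, 360)")
  }
  rt_bad <- !trials$omitted & (!is.finite(trials$rt_ms) | trials$rt_ms <= 0)
  if (any(rt_bad)) probs <- c(probs, "non-omitted trials must have rt_ms > 0")
  if (length(probs)) stop("invalid trial table: ", paste(probs, collapse = "; "))
  invisible(trials)
}

#' Analysis configuration
#'
#' @param tr trim proportion for robust tests.
#' @param min_trials minimum trials per cell for a mixture-model fit.
#' @param n_bins bins for the response-density chi-square.
#' @param expected_test_trials nominal test trials per task at pre/post.
#' @param expected_training_trials nominal trials per training session.
#' @param extra_trial_frac exclusion threshold: a participant whose extra
#'   (beyond-nominal) trial count strictly exceeds this fraction of the
#'   nominal count in any task is excluded.
#' @param rt_floor responses faster than this (ms) count as anticipations.
#' @param anticipation_max maximum tolerated anticipation proportion.
#' @param omission_max maximum tolerated omission proportion.
#' @param detection_correction apply the 1/(2n) rate correction.
#' @param seed integer seed recorded in the report.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(tr = 0.2, min_trials = 30L, n_bins = 8L,
                            expected_test_trials = 120L,
                            expected_training_trials = 360L,
                            extra_trial_frac = 0.1,
                            rt_floor = 200, anticipation_max = 0.2,
                            omission_max = 0.2,
                            detection_correction = FALSE,
                            seed = 1L) {
  structure(list(tr = tr, min_trials = min_trials, n_bins = n_bins,
                 expected_test_trials = expected_test_trials,
                 expected_training_trials = expected_training_trials,
                 extra_trial_frac = extra_trial_frac,
                 rt_floor = rt_floor, anticipation_max = anticipation_max,
                 omission_max = omission_max,
                 detection_correction = detection_correction,
                 seed = seed),
            class = "analysis_config")
}

#' Apply participant-level exclusion rules
#'
#' Three rules, applied per participant:
#' \itemize{
#'   \item `extra_trials`: in any phase x task, the number of logged test
#'     trials exceeds the nominal count by strictly more than
#'     `extra_trial_frac` (10%, i.e. more than 12 extra on a 120-trial
#'     task; exactly 12 extra is retained).
#'   \item `rt_criterion`: more than `anticipation_max` of a task's
#'     responses are faster than `rt_floor` ms.
#'   \item `omission_criterion`: more than `omission_max` of a task's
#'     trials are omissions.
#' }
#'
#' @param trials validated trial table.
#' @param config an [analysis_config()].
#' @return list with `trials` (rows of retained participants) and
#'   `report` (data.frame: participant_id, rule_triggered, detail).
#' @export
apply_exclusions <- function(trials, config = analysis_config()) {
  validate_trials(trials)
  t0 <- trials[!trials$practice, , drop = FALSE]
  rep_rows <- list()
  flag <- function(id, rule, detail) {
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      participant_id = id, rule_triggered = rule, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (id in unique(t0$participant_id)) {
    ti <- t0[t0$participant_id == id, , drop = FALSE]
    for (ph in unique(ti$phase)) {
      expected <- if (ph %in% c("pre", "post")) config$expected_test_trials
                  else config$expected_training_trials
      tp <- ti[ti$phase == ph, , drop = FALSE]
      for (task in unique(tp$task)) {
        tt <- tp[tp$task == task, , drop = FALSE]
        extra <- nrow(tt) - expected
        if (extra > config$extra_trial_frac * expected) {
          flag(id, "extra_trials",
               sprintf("%s/%s: %d trials logged, %d expected (%d extra)",
                       ph, task, nrow(tt), expected, extra))
        }
        resp <- tt[!tt$omitted, , drop = FALSE]
        if (nrow(resp) > 0) {
          ant <- mean(resp$rt_ms < config$rt_floor)
          if (ant > config$anticipation_max) {
            flag(id, "rt_criterion",
                 sprintf("%s/%s: %.0f%% responses < %g ms",
                         ph, task, 100 * ant, config$rt_floor))
          }
        }
        om <- mean(tt$omitted)
        if (om > config$omission_max) {
          flag(id, "omission_criterion",
               sprintf("%s/%s: %.0f%% omissions", ph, task, 100 * om))
        }
      }
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(participant_id = character(0), rule_triggered = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  keep <- !(trials$participant_id %in% unique(report$participant_id))
  if (!any(keep)) warning("apply_exclusions: every participant excluded")
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Fit every participant x phase x set-size cell
#'
#' Reproduction cells get a standard-mixture-model fit (two estimate rows:
#' `capacity_K` and `precision`); change-detection cells get Pashler's k;
#' visual-search cells get accuracy (omissions excluded) and mean RT over
#' correct responses. Cells below `min_trials`, or otherwise undefined,
#' are emitted with `value = NA` and `flagged = TRUE` rather than dropped.
#'
#' @param trials trial table (exclusions already applied; practice and,
#'   where appropriate, omitted trials are removed here).
#' @param config an [analysis_config()].
#' @return data.frame of cell estimates with provenance column
#'   `n_trials_used`.
#' @export
fit_all_cells <- function(trials, config = analysis_config()) {
  t0 <- trials[!trials$practice, , drop = FALSE]
  key <- unique(t0[, c("participant_id", "group", "phase", "task",
                       "set_size")])
  rows <- vector("list", 0L)
  emit <- function(k, type, value, n_used, flagged = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant_id = k$participant_id, group = k$group, phase = k$phase,
      task = k$task, set_size = k$set_size, estimate_type = type,
      value = value, n_trials_used = n_used, flagged = flagged,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(key))) {
    k <- key[i, ]
    cell <- t0[t0$participant_id == k$participant_id & t0$phase == k$phase &
                 t0$task == k$task & t0$set_size == k$set_size, , drop = FALSE]
    if (k$task %in% TASKS_REPRO) {
      cell <- cell[!cell$omitted, , drop = FALSE]
      n <- nrow(cell)
      if (n < config$min_trials) {
        emit(k, "capacity_K", NA_real_, n, TRUE)
        emit(k, "precision", NA_real_, n, TRUE)
        next
      }
      err <- wrap_error(cell$target_deg, cell$response_deg)
      fit <- suppressWarnings(
        fit_smm(err, set_size = k$set_size, min_trials = config$min_trials))
      emit(k, "capacity_K", fit$capacity_k, n, fit$boundary)
      emit(k, "precision", fit$precision, n, fit$boundary)
    } else if (k$task == "change_detection") {
      cell <- cell[!cell$omitted, , drop = FALSE]
      ch <- cell$change_trial
      said_change <- cell$response_key == "change"
      hits <- sum(ch & said_change); misses <- sum(ch & !said_change)
      fas <- sum(!ch & said_change); crs <- sum(!ch & !said_change)
      if (hits + misses < 1 || fas + crs < 1) {
        emit(k, "pashler_k", NA_real_, nrow(cell), TRUE)
        next
      }
      s <- rates_from_counts(hits, misses, fas, crs, set_size = k$set_size,
                             correction = config$detection_correction)
      if (s$FA >= 1) {
        emit(k, "pashler_k", NA_real_, nrow(cell), TRUE)
      } else {
        emit(k, "pashler_k", pashler_k(s)$k, nrow(cell))
      }
    } else if (k$task == "visual_search") {
      resp <- cell[!cell$omitted, , drop = FALSE]
      if (nrow(resp) == 0) {
        emit(k, "accuracy", NA_real_, 0, TRUE)
        emit(k, "mean_rt", NA_real_, 0, TRUE)
        next
      }
      emit(k, "accuracy", mean(resp$correct), nrow(resp))
      corr <- resp[resp$correct, , drop = FALSE]
      emit(k, "mean_rt", if (nrow(corr)) mean(corr$rt_ms) else NA_real_,
           nrow(corr), flagged = nrow(corr) == 0)
    }
  }
  do.call(rbind, rows)
}

#' Chi-square comparison of two response distributions
#'
#' Bins responses (degrees, [0, 360)) into `n_bins` equal-width bins
#' anchored at `anchor` degrees and runs a Pearson chi-square test of
#' homogeneity on the resulting 2 x n_bins table (df = n_bins - 1, no
#' continuity correction). With the default 8 bins the df is 7. Used to
#' ask whether two pools of responses (e.g. the two groups at post-test)
#' favour the same orientations.
#'
#' @param responses_a,responses_b response angles in degrees.
#' @param n_bins number of bins (>= 2).
#' @param anchor left edge of the first bin, degrees.
#' @return a `vwm_test`; `extra$N` is the pooled response count.
#' @export
density_comparison <- function(responses_a, responses_b, n_bins = 8L,
                               anchor = 0) {
  if (n_bins < 2) stop("density_comparison: n_bins must be >= 2")
  if (!length(responses_a) || !length(responses_b)) {
    stop("density_comparison: empty response group")
  }
  edges <- seq(0, 360, length.out = n_bins + 1L)
  cut_counts <- function(x) {
    x <- (x - anchor) %% 360
    tabulate(findInterval(x, edges, rightmost.closed = FALSE,
                          all.inside = TRUE), nbins = n_bins)
  }
  obs <- rbind(cut_counts(responses_a), cut_counts(responses_b))
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(E == 0)) stop("density_comparison: empty bin margin")
  stat <- sum((obs - E)^2 / E)
  df <- n_bins - 1L
  .test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
               method = "density_chi2",
               extra = list(N = sum(obs), n_bins = n_bins, observed = obs))
}

# ---- full analysis ---------------------------------------------------------

.test_row <- function(label, tst, bf = NULL) {
  data.frame(measure = label, method = tst$method,
             statistic = tst$statistic,
             df1 = tst$df[1L], df2 = if (length(tst$df) > 1) tst$df[2L] else NA,
             p = tst$p,
             delta_t = if (!is.null(tst$effect$delta_t)) tst$effect$delta_t else NA,
             bf10 = if (!is.null(bf)) bf$bf10 else NA,
             bf_method = if (!is.null(bf)) bf$method else NA_character_,
             stringsAsFactors = FALSE)
}

.anova_rows <- function(label, av, n_obs_fun = NULL) {
  tb <- av$table
  tb$measure <- label
  # BIC-approximate Bayes factor per effect, from its own error stratum:
  # n_eff observations, SSE_reduced = SS_eff + SS_err, SSE_full = SS_err
  tb$bf10 <- NA_real_
  tb$bf_method <- "bic_approx"
  for (i in seq_len(nrow(tb))) {
    n_eff <- tb$df1[i] + tb$df2[i] + 1
    d_bic <- n_eff * log((tb$ss[i] + tb$ss_error[i]) / tb$ss_error[i]) -
      tb$df1[i] * log(n_eff)
    tb$bf10[i] <- bic_bf_approx(0, -d_bic)$bf10
  }
  tb$method <- av$method
  tb[, c("measure", "effect", "method", "df1", "df2", "statistic", "p",
         "eta_g", "eta_p", "bf10", "bf_method")]
}

# wide table of one estimate per participant for a given measure
.cells_wide <- function(cells, task, type, phases, set_size = NULL) {
  sel <- cells$task == task & cells$estimate_type == type &
    cells$phase %in% phases & !cells$flagged & !is.na(cells$value)
  if (!is.null(set_size)) sel <- sel & cells$set_size == set_size
  cells[sel, c("participant_id", "group", "phase", "set_size", "value")]
}

.measures <- function(cells) {
  u <- unique(cells[, c("task", "estimate_type")])
  u[order(u$task, u$estimate_type), ]
}

#' Run the complete analysis pipeline
#'
#' Reproduces the full analysis graph on any trial table with the
#' canonical schema: exclusions; per-cell estimates; descriptive tables;
#' baseline (pre-test) robust group comparisons with JZS Bayes factors;
#' training-phase repeated-measures ANOVAs (session x set size, per
#' group and measure); pre/post two-way mixed ANOVAs per measure;
#' follow-up within-group paired and between-group independent Yuen tests
#' with AKP effect sizes; and response-density comparisons between groups
#' at each test phase. ANOVA Bayes factors are BIC approximations and are
#' tagged `bic_approx` throughout; every statistic carries its method tag.
#'
#' @param trials trial table (canonical schema).
#' @param config an [analysis_config()].
#' @return a `vwm_report`: nested list of data.frames.
#' @export
run_full_analysis <- function(trials, config = analysis_config()) {
  validate_trials(trials)
  excl <- apply_exclusions(trials, config)
  cells <- fit_all_cells(excl$trials, config)

  # descriptives: Tables-4/5-shaped summary of cell estimates
  agg <- stats::aggregate(
    value ~ group + phase + task + set_size + estimate_type,
    data = cells[!cells$flagged & !is.na(cells$value), ],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  descriptives <- cbind(agg[, 1:5], as.data.frame(agg$value))

  phases_here <- unique(cells$phase)
  has_prepost <- all(c("pre", "post") %in% phases_here)
  training_phases <- intersect(c("s1", "s2", "s3", "s4"), phases_here)
  meas <- .measures(cells)

  baseline <- NULL
  prepost_anova <- NULL
  followup <- NULL
  density <- NULL
  training <- NULL

  if (has_prepost) {
    base_rows <- list(); pp_rows <- list(); fu_rows <- list()
    for (i in seq_len(nrow(meas))) {
      task <- meas$task[i]; type <- meas$estimate_type[i]
      lab <- paste(task, type, sep = ".")
      w <- .cells_wide(cells, task, type, c("pre", "post"))
      # keep participants with both phases
      both <- intersect(w$participant_id[w$phase == "pre"],
                        w$participant_id[w$phase == "post"])
      w <- w[w$participant_id %in% both, ]
      if (length(both) < 4) next
      pre <- w[w$phase == "pre", ]
      xs <- pre$value[pre$group == "experimental"]
      ys <- pre$value[pre$group == "control"]
      if (length(xs) >= 4 && length(ys) >= 4) {
        tst <- yuen_independent(xs, ys, config$tr)
        bf <- jzs_bf_ttest(tst$statistic, tst$h[1L], tst$h[2L])
        base_rows[[length(base_rows) + 1L]] <- .test_row(lab, tst, bf)
        av <- mixed_anova(w, participant = "participant_id",
                          group = "group", time = "phase")
        pp_rows[[length(pp_rows) + 1L]] <- .anova_rows(lab, av)
        # follow-ups: within each group pre vs post, and groups at post
        for (grp in c("experimental", "control")) {
          wg <- w[w$group == grp, ]
          xpre <- wg$value[wg$phase == "pre"][order(wg$participant_id[wg$phase == "pre"])]
          xpost <- wg$value[wg$phase == "post"][order(wg$participant_id[wg$phase == "post"])]
          tstp <- yuen_paired(xpre, xpost, config$tr)
          bfp <- jzs_bf_ttest(tstp$statistic, tstp$h)
          fu_rows[[length(fu_rows) + 1L]] <-
            .test_row(paste0(lab, ".", grp, ".pre_vs_post"), tstp, bfp)
        }
        post <- w[w$phase == "post", ]
        tstb <- yuen_independent(post$value[post$group == "experimental"],
                                 post$value[post$group == "control"],
                                 config$tr)
        bfb <- jzs_bf_ttest(tstb$statistic, tstb$h[1L], tstb$h[2L])
        fu_rows[[length(fu_rows) + 1L]] <-
          .test_row(paste0(lab, ".groups_at_post"), tstb, bfb)
      }
    }
    baseline <- if (length(base_rows)) do.call(rbind, base_rows)
    prepost_anova <- if (length(pp_rows)) do.call(rbind, pp_rows)
    followup <- if (length(fu_rows)) do.call(rbind, fu_rows)

    # response-density comparison between groups at each test phase
    t0 <- excl$trials[!excl$trials$practice, ]
    repro <- t0[t0$task == "orientation_reproduction" &
                  t0$phase %in% c("pre", "post") & !t0$omitted, ]
    if (nrow(repro)) {
      dens_rows <- list()
      for (ph in c("pre", "post")) {
        ra <- repro$response_deg[repro$phase == ph &
                                   repro$group == "experimental"]
        rb <- repro$response_deg[repro$phase == ph & repro$group == "control"]
        if (length(ra) && length(rb)) {
          tst <- density_comparison(ra, rb, config$n_bins)
          dens_rows[[length(dens_rows) + 1L]] <-
            cbind(.test_row(paste0("orientation_responses.", ph), tst),
                  N = tst$N)
        }
      }
      density <- if (length(dens_rows)) do.call(rbind, dens_rows)
    }
  }

  if (length(training_phases) >= 2) {
    tr_rows <- list()
    for (i in seq_len(nrow(meas))) {
      task <- meas$task[i]; type <- meas$estimate_type[i]
      lab <- paste(task, type, sep = ".")
      w <- cells[cells$task == task & cells$estimate_type == type &
                   cells$phase %in% training_phases & !cells$flagged &
                   !is.na(cells$value), ]
      if (!nrow(w)) next
      for (grp in unique(w$group)) {
        wg <- w[w$group == grp, ]
        if (length(unique(wg$set_size)) < 2) next
        cnt <- table(wg$participant_id)
        full <- names(cnt)[cnt == length(training_phases) *
                             length(unique(wg$set_size))]
        wg <- wg[wg$participant_id %in% full, ]
        if (length(full) < 4) next
        av <- rm_anova_2within(wg, participant = "participant_id",
                               factorA = "phase", factorB = "set_size")
        tr_rows[[length(tr_rows) + 1L]] <- .anova_rows(paste0(lab, ".", grp), av)
      }
    }
    training <- if (length(tr_rows)) do.call(rbind, tr_rows)
  }

  structure(list(
    exclusions = excl$report,
    n_retained = length(unique(excl$trials$participant_id)),
    cell_estimates = cells,
    descriptives = descriptives,
    baseline = baseline,
    training_anova = training,
    prepost_anova = prepost_anova,
    followup = followup,
    density = density,
    config = unclass(config)
  ), class = "vwm_report")
}

#' @export
print.vwm_report <- function(x, ...) {
  cat("Visual WM training-study analysis report\n")
  cat("  participants retained:", x$n_retained,
      "(", nrow(x$exclusions), "exclusion flags )\n")
  for (s in c("baseline", "training_anova", "prepost_anova", "followup",
              "density")) {
    if (!is.null(x[[s]])) cat(sprintf("  %s: %d rows\n", s, nrow(x[[s]])))
  }
  invisible(x)
}

#' Write a report to disk (JSON + CSV tables)
#'
#' @param report a `vwm_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), paths, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  for (s in c("cell_estimates", "descriptives", "baseline", "training_anova",
              "prepost_anova", "followup", "density", "exclusions")) {
    if (!is.null(report[[s]]) && is.data.frame(report[[s]])) {
      p <- file.path(dir, paste0(s, ".csv"))
      utils::write.csv(report[[s]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read / write the canonical trial CSV
#'
#' @param path file path.
#' @return data.frame of trials.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$practice <- as.logical(tr$practice)
  tr$omitted <- as.logical(tr$omitted)
  if ("change_trial" %in% names(tr)) tr$change_trial <- as.logical(tr$change_trial)
  validate_trials(tr)
  tr
}

#' @rdname read_trials
#' @param trials trial table.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
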
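make_clean <- function(seed = 1, scenario = "null") {
  simulate_study(tiny_study_config(seed = seed, scenario = scenario))
}

test_that("validate_trials rejects malformed tables before any statistics run", {
  tr <- make_clean()
  expect_silent(validate_trials(tr))
  expect_error(validate_trials(tr[, -1]), "missing columns")
  bad <- tr; bad$response_deg[1] <- 400
  expect_error(validate_trials(bad), "degrees")
  bad2 <- tr; bad2$rt_ms[5] <- -3
  expect_error(validate_trials(bad2), "rt_ms")
  expect_error(run_full_analysis(tr[, -2]), "missing columns")
})

test_that("extra-trial exclusion reads 'exceeded' strictly", {
  cfg <- tiny_analysis_config()  # 60 nominal trials -> threshold 6 extra
  tr <- make_clean()
  dup <- tr[tr$participant_id == "E01" & tr$phase == "pre", ][1:7, ]
  r <- apply_exclusions(rbind(tr, dup), cfg)  # 7 extra > 6: excluded
  expect_true("E01" %in% r$report$participant_id)
  expect_equal(unique(r$report$rule_triggered), "extra_trials")
  expect_false("E01" %in% r$trials$participant_id)
  r2 <- apply_exclusions(rbind(tr, dup[1:6, ]), cfg)  # exactly 6: retained
  expect_false("E01" %in% r2$report$participant_id)
  # clean data: zero exclusions
  r3 <- apply_exclusions(tr, cfg)
  expect_equal(nrow(r3$report), 0)
  expect_equal(nrow(r3$trials), nrow(tr))
})

test_that("RT and omission criteria flag non-compliant participants", {
  tr <- make_clean()
  fast <- tr$participant_id == "C02" & tr$phase == "pre"
  tr$rt_ms[fast][1:20] <- 50  # a third of C02's pre trials are anticipations
  r <- apply_exclusions(tr, tiny_analysis_config())
  expect_true(any(r$report$participant_id == "C02" &
                    r$report$rule_triggered == "rt_criterion"))
  tr2 <- make_clean()
  om <- which(tr2$participant_id == "C03" & tr2$phase == "post")[1:20]
  tr2$omitted[om] <- TRUE
  tr2$rt_ms[om] <- NA
  tr2$response_deg[om] <- NA
  r2 <- apply_exclusions(tr2, tiny_analysis_config())
  expect_true(any(r2$report$participant_id == "C03" &
                    r2$report$rule_triggered == "omission_criterion"))
})

test_that("fit_all_cells recovers the generating cell parameters", {
  cfg <- tiny_study_config(seed = 30)
  tr <- simulate_study(cfg)
  cells <- fit_all_cells(tr, tiny_analysis_config())
  expect_true(all(c("n_trials_used", "estimate_type") %in% names(cells)))
  expect_true(all(cells$n_trials_used > 0))
  kk <- cells$value[cells$estimate_type == "capacity_K" & cells$phase == "pre"]
  # truth: g = .39 at N = 4 -> K = 2.44; cell means off by < .35 at n=12x60
  expect_lt(abs(mean(kk) - capacity_from_g(0.39, 4)), 0.35)
  pp <- cells$value[cells$estimate_type == "precision" & cells$phase == "pre"]
  expect_lt(abs(mean(pp) - 1 / 16.7), 0.01)
})

test_that("fit_all_cells flags undefined cells instead of dropping them", {
  tr <- make_clean()
  # a reproduction cell below min_trials
  keep <- !(tr$participant_id == "E02" & tr$phase == "post")
  short <- tr[tr$participant_id == "E02" & tr$phase == "post", ][1:10, ]
  cells <- fit_all_cells(rbind(tr[keep, ], short), tiny_analysis_config())
  flagged <- cells[cells$participant_id == "E02" & cells$phase == "post", ]
  expect_true(all(flagged$flagged))
  expect_true(all(is.na(flagged$value)))
  expect_equal(unique(flagged$n_trials_used), 10)
})

test_that("detection and search cells compute their headline measures", {
  det <- data.frame(
    participant_id = "P1", group = "experimental", phase = "pre",
    task = "change_detection", set_size = 4, practice = FALSE,
    target_deg = NA, response_deg = NA,
    change_trial = rep(c(TRUE, FALSE), each = 30),
    response_key = rep(c("change", "match"), each = 30),
    rt_ms = 800, omitted = FALSE, stringsAsFactors = FALSE)
  cells <- fit_all_cells(det)
  expect_equal(cells$value[cells$estimate_type == "pashler_k"], 4)
  # all-omission search cell: flagged, not dropped
  srch <- data.frame(
    participant_id = "P2", group = "control", phase = "pre",
    task = "visual_search", set_size = 16, practice = FALSE,
    target_deg = NA, response_deg = NA, change_trial = TRUE,
    response_key = NA, rt_ms = NA, omitted = TRUE, stringsAsFactors = FALSE)
  srch <- srch[rep(1, 40), ]
  cells2 <- fit_all_cells(srch)
  expect_true(all(cells2$flagged))
  expect_true(all(is.na(cells2$value)))
})

test_that("density_comparison bins at 45 degrees and detects peaked responding", {
  set.seed(60)
  a <- runif(3600, 0, 360)
  r <- density_comparison(a, runif(3600, 0, 360))
  expect_equal(r$df, 7)
  expect_equal(r$N, 7200)
  # group concentrated at the four oblique orientations vs uniform; with the
  # default 0-degree anchor those peaks straddle bin edges and split evenly,
  # so the power check uses an anchor that centres the bins on the peaks
  b <- (sample(c(45, 135, 225, 315), 3600, replace = TRUE) +
          rnorm(3600, 0, 8)) %% 360
  r2 <- density_comparison(runif(3600, 0, 360), b, anchor = 22.5)
  expect_lt(r2$p, 0.001)
  expect_error(density_comparison(numeric(0), a), "empty")
  expect_equal(density_comparison(a, b, n_bins = 12)$df, 11)
})

test_that("run_full_analysis produces the full tagged report", {
  tr <- simulate_study(tiny_study_config(seed = 70, scenario = "quality_gain"))
  rep <- run_full_analysis(tr, tiny_analysis_config())
  expect_s3_class(rep, "vwm_report")
  expect_equal(rep$n_retained, 12)
  expect_true(all(c("capacity_K", "precision") %in%
                    rep$cell_estimates$estimate_type))
  # every statistic carries a method tag; approximations are labelled
  expect_true(all(rep$baseline$method == "yuen_independent"))
  expect_true(all(rep$prepost_anova$bf_method == "bic_approx"))
  expect_true(all(rep$followup$method %in%
                    c("yuen_paired", "yuen_independent")))
  expect_equal(nrow(rep$density), 2)
  expect_true(all(rep$prepost_anova$df1 == 1))
  expect_true(all(rep$prepost_anova$df2 == 10))  # 12 participants - 2
})

test_that("the pipeline is deterministic and reports are byte-identical", {
  tr <- make_clean(seed = 80)
  r1 <- run_full_analysis(tr, tiny_analysis_config())
  r2 <- run_full_analysis(tr, tiny_analysis_config())
  expect_identical(r1, r2)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_report(r1, d1); write_report(r2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
})

test_that("trial CSV round-trips through the canonical schema", {
  tr <- make_clean(seed = 90)
  p <- tempfile(fileext = ".csv")
  write_trials(tr, p)
  tr2 <- read_trials(p)
  expect_equal(nrow(tr2), nrow(tr))
  expect_equal(tr2$response_deg, tr$response_deg, tolerance = 1e-12)
  expect_identical(tr2$practice, tr$practice)
})

test_that("the CLI drives simulate, fit and analyze end to end", {
  td <- tempdir()
  cfgp <- file.path(td, "cfg.json")
  jsonlite::write_json(list(n_experimental = 4, n_control = 4,
                            phases = c("pre", "post"),
                            tasks = "orientation_reproduction",
                            trials_per_cell = 40, practice_trials = 0),
                       cfgp, auto_unbox = TRUE)
  trp <- file.path(td, "trials.csv")
  expect_message(vwm_cli(c("simulate", "--config", cfgp, "--out", trp,
                           "--seed", "3")), "wrote")
  cellp <- file.path(td, "cells.csv")
  expect_message(vwm_cli(c("fit", "--trials", trp, "--out", cellp)), "cell")
  expect_true(file.exists(cellp))
  acfg <- file.path(td, "acfg.json")
  jsonlite::write_json(list(expected_test_trials = 40), acfg,
                       auto_unbox = TRUE)
  repdir <- file.path(td, "report")
  expect_message(vwm_cli(c("analyze", "--trials", trp, "--report", repdir,
                           "--config", acfg)), "report")
  expect_true(file.exists(file.path(repdir, "report.json")))
})
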
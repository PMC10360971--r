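test_that("trimmed_mean trims symmetrically and resists outliers", {
  expect_equal(trimmed_mean(1:10, 0.2), 5.5)
  x <- rnorm(25)
  expect_equal(trimmed_mean(x, 0), mean(x))
  y <- 1:10; y[which.max(y)] <- 1e6
  expect_equal(trimmed_mean(y, 0.2), trimmed_mean(1:10, 0.2))
  expect_error(trimmed_mean(numeric(0)), "empty")
  expect_error(trimmed_mean(1:5, 0.5), "tr")
})

test_that("yuen_independent at tr = 0 is exactly Welch's t-test", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(10 + i * 3, sd = 1 + i / 4)
    y <- rnorm(25 - i, mean = 0.3)
    ours <- yuen_independent(x, y, tr = 0)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("yuen_independent matches the textbook formula step by step", {
  set.seed(32)
  x <- rnorm(30); y <- rnorm(34, 0.4)
  tr <- 0.2
  ours <- yuen_independent(x, y, tr)
  # independent evaluation of Yuen's statistic
  wins <- function(v) {
    n <- length(v); g <- floor(tr * n); vs <- sort(v)
    pmin(pmax(v, vs[g + 1]), vs[n - g])
  }
  h1 <- 30 - 2 * floor(tr * 30); h2 <- 34 - 2 * floor(tr * 34)
  d1 <- 29 * var(wins(x)) / (h1 * (h1 - 1))
  d2 <- 33 * var(wins(y)) / (h2 * (h2 - 1))
  t_ref <- (mean(sort(x)[7:24]) - mean(sort(y)[7:28])) / sqrt(d1 + d2)
  df_ref <- (d1 + d2)^2 / (d1^2 / (h1 - 1) + d2^2 / (h2 - 1))
  expect_equal(ours$statistic, t_ref, tolerance = 1e-12)
  expect_equal(ours$df, df_ref, tolerance = 1e-12)
  expect_true(ours$df > 28 && ours$df < 62)
})

test_that("yuen_paired has df = h - 1 (17 at n = 30, 21 at n = 34)", {
  set.seed(33)
  expect_equal(yuen_paired(rnorm(30), rnorm(30))$df, 17)
  expect_equal(yuen_paired(rnorm(34), rnorm(34))$df, 21)
  x <- rnorm(20)
  r <- yuen_paired(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(yuen_paired(rnorm(10), rnorm(11)), "paired")
})

test_that("akp_delta matches its definition and is scale invariant", {
  set.seed(34)
  x <- rnorm(30); y <- rnorm(34, 0.5)
  tr <- 0.2
  wins <- function(v) {
    n <- length(v); g <- floor(tr * n); vs <- sort(v)
    pmin(pmax(v, vs[g + 1]), vs[n - g])
  }
  s2p <- (29 * var(wins(x)) + 33 * var(wins(y))) / 62
  ref <- 0.642 * (mean(sort(x)[7:24]) - mean(sort(y)[7:28])) / sqrt(s2p)
  expect_equal(akp_delta(x, y), ref, tolerance = 1e-4)  # 0.642 is rounded
  expect_equal(akp_delta(3.7 * x, 3.7 * y), akp_delta(x, y), tolerance = 1e-12)
  xt <- c(1, 1, 1, 2, 3, 3, 3)
  expect_equal(akp_delta(xt, xt + 0), 0)
  expect_error(akp_delta(rep(1, 10), rep(1, 10)), "zero")
})

test_that("chi2_2x2 reproduces the demographic contingency statistic", {
  tab <- matrix(c(8, 17, 22, 17), 2, 2)  # gender counts by group
  r <- chi2_2x2(tab)
  expect_equal(round(r$statistic, 2), 2.73)
  expect_lt(abs(r$p - 0.098), 5e-4)
  # proportional table: clamped correction gives exactly zero
  expect_equal(chi2_2x2(matrix(c(10, 20, 20, 40), 2, 2))$statistic, 0)
  # symmetry under row swap and transposition
  expect_equal(chi2_2x2(tab[2:1, ])$statistic, r$statistic)
  expect_equal(chi2_2x2(t(tab))$statistic, r$statistic)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 6), 2, 2, byrow = TRUE)), "margin")
})

test_that("mixed_anova reports (1, 62) for 64 participants, 2 groups, 2 times", {
  set.seed(35)
  d <- data.frame(participant = rep(1:64, each = 2),
                  group = rep(rep(c("e", "c"), c(30, 34)), each = 2),
                  time = rep(c("pre", "post"), 64),
                  value = rnorm(128))
  a <- mixed_anova(d)
  expect_equal(a$table$df1, c(1, 1, 1))
  expect_equal(a$table$df2, c(62, 62, 62))
  expect_error(mixed_anova(d[-1, ]), "exactly one observation")
})

test_that("mixed_anova agrees with aov on a balanced design", {
  set.seed(36)
  d <- data.frame(participant = factor(rep(1:20, each = 2)),
                  group = factor(rep(rep(c("e", "c"), each = 10), each = 2)),
                  time = factor(rep(c("pre", "post"), 20)),
                  value = rnorm(40) + rep(rnorm(20), each = 2))
  m <- mixed_anova(d)
  s <- summary(aov(value ~ group * time + Error(participant / time), data = d))
  f_ref <- c(s[[1]][[1]]$`F value`[1], s[[2]][[1]]$`F value`[1:2])
  expect_equal(m$table$statistic[match(c("group", "time", "time:group"),
                                       m$table$effect)],
               f_ref, tolerance = 1e-10)
})

test_that("with no within-subject change, F_group is the squared pooled t", {
  set.seed(37)
  m_i <- rnorm(24, mean = rep(c(0, 0.8), c(10, 14)))
  d <- data.frame(participant = rep(1:24, each = 2),
                  group = rep(rep(c("e", "c"), c(10, 14)), each = 2),
                  time = rep(c("pre", "post"), 24),
                  value = rep(m_i, each = 2))
  a <- mixed_anova(d)
  tt <- t.test(m_i[1:10], m_i[11:24], var.equal = TRUE)
  expect_equal(a$table$statistic[a$table$effect == "group"],
               unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("mixed_anova sums of squares are additive", {
  set.seed(38)
  d <- data.frame(participant = rep(1:30, each = 2),
                  group = rep(rep(c("e", "c"), c(13, 17)), each = 2),
                  time = rep(c("pre", "post"), 30),
                  value = rnorm(60))
  a <- mixed_anova(d)
  expect_equal(sum(a$decomp$ss), sum((d$value - mean(d$value))^2),
               tolerance = 1e-8)
})

test_that("rm_anova_2within reports the classical dfs and agrees with aov", {
  set.seed(39)
  d <- expand.grid(participant = 1:30, factorA = 1:4, factorB = 1:3)
  d$value <- rnorm(nrow(d)) + rep(rnorm(30), 12)
  a <- rm_anova_2within(d)
  i <- match(c("factorA", "factorB", "factorA:factorB"), a$table$effect)
  expect_equal(a$table$df1[i], c(3, 2, 6))
  expect_equal(a$table$df2[i], c(87, 58, 174))
  d$participant <- factor(d$participant)
  d$factorA <- factor(d$factorA); d$factorB <- factor(d$factorB)
  s <- summary(aov(value ~ factorA * factorB +
                     Error(participant / (factorA * factorB)), data = d))
  f_ref <- c(s[["Error: participant:factorA"]][[1]]$`F value`[1],
             s[["Error: participant:factorB"]][[1]]$`F value`[1],
             s[["Error: participant:factorA:factorB"]][[1]]$`F value`[1])
  expect_equal(a$table$statistic[i], f_ref, tolerance = 1e-10)
  expect_error(rm_anova_2within(d[-1, ]), "incomplete")
})

test_that("eta_squared orders its two variants and matches hand-computed ratios", {
  decomp <- data.frame(
    term = c("A", "A_err", "B", "B_err", "subj"),
    ss = c(10, 40, 5, 20, 35),
    is_error = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    error_term = c("A_err", NA, "B_err", NA, NA))
  e <- eta_squared(decomp)
  expect_equal(e$eta_p[e$term == "A"], 10 / 50)
  expect_equal(e$eta_g[e$term == "A"], 10 / (10 + 95))
  expect_true(all(e$eta_p >= e$eta_g))
  # one-way between design: single error term, the two variants coincide
  one <- data.frame(term = c("grp", "resid"), ss = c(12, 48),
                    is_error = c(FALSE, TRUE), error_term = c("resid", NA))
  e1 <- eta_squared(one)
  expect_equal(e1$eta_g, e1$eta_p)
  bad <- decomp; bad$ss[1] <- -2
  expect_error(eta_squared(bad), "negative")
})

test_that("null p-values are uniform (Kolmogorov-Smirnov)", {
  set.seed(40)
  p_yp <- replicate(2000, yuen_paired(rnorm(30), rnorm(30))$p)
  expect_gt(ks.test(p_yp, "punif")$p.value, 0.01)
  p_yi <- replicate(2000, yuen_independent(rnorm(30), rnorm(34))$p)
  expect_gt(ks.test(p_yi, "punif")$p.value, 0.01)
})
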
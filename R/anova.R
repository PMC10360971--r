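# ANOVA layer: two-way mixed (one between, one within factor) and
# two-way fully repeated-measures designs, with generalized and partial
# eta squared. Univariate F tests with effect-specific subject-interaction
# error terms; no sphericity correction is applied (two-level within
# factors need none, and multi-level dfs are reported uncorrected).

#' Generalized and partial eta squared from a sums-of-squares decomposition
#'
#' Partial eta squared divides each effect SS by (SS_effect + SS of its
#' own error term). Generalized eta squared, under the convention for
#' designs in which every factor is manipulated, divides by (SS_effect +
#' the sum of ALL subject-related error SS in the design), making effect
#' sizes comparable across designs.
#'
#' @param decomp data.frame with columns `term` (character), `ss`
#'   (nonnegative), `is_error` (logical), and, for effect rows,
#'   `error_term` (the `term` of the error row the effect is tested
#'   against).
#' @return data.frame with columns `term`, `eta_g`, `eta_p` (effect rows
#'   only).
#' @export
eta_squared <- function(decomp) {
  stopifnot(is.data.frame(decomp),
            all(c("term", "ss", "is_error") %in% names(decomp)))
  if (any(decomp$ss < -1e-8)) stop("eta_squared: negative sum of squares")
  decomp$ss <- pmax(decomp$ss, 0)
  err_total <- sum(decomp$ss[decomp$is_error])
  eff <- decomp[!decomp$is_error, , drop = FALSE]
  ss_err_own <- vapply(eff$error_term, function(e) {
    i <- match(e, decomp$term)
    if (is.na(i)) stop("eta_squared: unknown error term '", e, "'")
    decomp$ss[i]
  }, numeric(1))
  data.frame(term = eff$term,
             eta_g = eff$ss / (eff$ss + err_total),
             eta_p = eff$ss / (eff$ss + ss_err_own),
             row.names = NULL)
}

.check_cols <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
}

#' Two-way mixed ANOVA (between-subjects group, within-subjects time)
#'
#' Classical univariate mixed-model ANOVA for a design with one
#' between-subjects factor and one within-subjects factor observed once
#' per participant per level. Group is tested against subjects-within-
#' groups; the within effect and the interaction against the
#' time-by-subject error. With 64 participants in 2 groups and 2 time
#' points every effect has df (1, 62).
#'
#' @param data long-format data.frame.
#' @param participant,group,time,value column names.
#' @return object of class `vwm_anova`: list with `$table` (effect, df1,
#'   df2, ss, ss_error, statistic, p, eta_g, eta_p) and `$decomp`.
#' @export
mixed_anova <- function(data, participant = "participant", group = "group",
                        time = "time", value = "value") {
  .check_cols(data, c(participant, group, time, value))
  id <- factor(data[[participant]])
  gr <- factor(data[[group]])
  tm <- factor(data[[time]])
  y <- data[[value]]
  if (any(!is.finite(y))) stop("mixed_anova: non-finite values")

  tab <- table(id, tm)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[rowSums(tab != 1L) > 0]
    stop("mixed_anova: participants without exactly one observation per time: ",
         paste(bad, collapse = ", "))
  }
  g_of_id <- tapply(as.character(gr), id, function(z) {
    u <- unique(z)
    if (length(u) != 1L) stop("mixed_anova: participant in more than one group")
    u
  })
  N <- nlevels(id); G <- nlevels(gr); Tt <- nlevels(tm)
  n_g <- table(factor(g_of_id, levels = levels(gr)))

  grand <- mean(y)
  m_i <- tapply(y, id, mean)
  y_g <- tapply(y, gr, mean)
  y_t <- tapply(y, tm, mean)
  y_gt <- tapply(y, list(gr, tm), mean)

  ss_total <- sum((y - grand)^2)
  ss_bs <- Tt * sum((m_i - grand)^2)
  ss_group <- Tt * sum(n_g * (y_g - grand)^2)
  ss_subj <- ss_bs - ss_group
  ss_time <- N * sum((y_t - grand)^2)
  ss_tg <- sum(outer(as.numeric(n_g), rep(1, Tt)) *
                 (y_gt - outer(as.numeric(y_g), rep(1, Tt)) -
                    outer(rep(1, G), as.numeric(y_t)) + grand)^2)
  ss_tsubj <- ss_total - ss_bs - ss_time - ss_tg

  decomp <- data.frame(
    term = c("group", "subjects_within_groups", "time", "time:group",
             "time:subjects"),
    ss = c(ss_group, ss_subj, ss_time, ss_tg, ss_tsubj),
    is_error = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    error_term = c("subjects_within_groups", NA, "time:subjects",
                   "time:subjects", NA),
    df = c(G - 1, N - G, Tt - 1, (Tt - 1) * (G - 1), (Tt - 1) * (N - G)),
    stringsAsFactors = FALSE)

  .anova_table(decomp, method = "mixed_anova")
}

#' Two-way repeated-measures ANOVA (two within-subjects factors)
#'
#' Fully within-subjects two-factor design with a complete crossing per
#' participant, analysed with the classical univariate decomposition in
#' which each effect is tested against its own interaction with subjects.
#' No sphericity correction. With n = 30 participants, a 4-level factor A
#' and a 3-level factor B the dfs are (3, 87), (2, 58), and (6, 174).
#'
#' @param data long-format data.frame.
#' @param participant,factorA,factorB,value column names.
#' @return object of class `vwm_anova` (see [mixed_anova()]).
#' @export
rm_anova_2within <- function(data, participant = "participant",
                             factorA = "factorA", factorB = "factorB",
                             value = "value") {
  .check_cols(data, c(participant, factorA, factorB, value))
  id <- factor(data[[participant]])
  A <- factor(data[[factorA]])
  B <- factor(data[[factorB]])
  y <- data[[value]]
  if (any(!is.finite(y))) stop("rm_anova_2within: non-finite values")
  tab <- table(id, A, B)
  if (any(tab != 1L)) stop("rm_anova_2within: incomplete or duplicated crossing")

  n <- nlevels(id); a <- nlevels(A); b <- nlevels(B)
  grand <- mean(y)
  m_i <- tapply(y, id, mean)
  y_a <- tapply(y, A, mean)
  y_b <- tapply(y, B, mean)
  y_ab <- tapply(y, list(A, B), mean)
  y_ia <- tapply(y, list(id, A), mean)
  y_ib <- tapply(y, list(id, B), mean)

  ss_total <- sum((y - grand)^2)
  ss_subj <- a * b * sum((m_i - grand)^2)
  ss_A <- n * b * sum((y_a - grand)^2)
  ss_B <- n * a * sum((y_b - grand)^2)
  ss_AB <- n * sum((y_ab - outer(as.numeric(y_a), rep(1, b)) -
                      outer(rep(1, a), as.numeric(y_b)) + grand)^2)
  ss_Asubj <- b * sum((y_ia - outer(as.numeric(m_i), rep(1, a)) -
                         outer(rep(1, n), as.numeric(y_a)) + grand)^2)
  ss_Bsubj <- a * sum((y_ib - outer(as.numeric(m_i), rep(1, b)) -
                         outer(rep(1, n), as.numeric(y_b)) + grand)^2)
  ss_ABsubj <- ss_total - ss_subj - ss_A - ss_B - ss_AB - ss_Asubj - ss_Bsubj

  decomp <- data.frame(
    term = c("subjects", "factorA", "factorA:subjects", "factorB",
             "factorB:subjects", "factorA:factorB",
             "factorA:factorB:subjects"),
    ss = c(ss_subj, ss_A, ss_Asubj, ss_B, ss_Bsubj, ss_AB, ss_ABsubj),
    is_error = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    error_term = c(NA, "factorA:subjects", NA, "factorB:subjects", NA,
                   "factorA:factorB:subjects", NA),
    df = c(n - 1, a - 1, (a - 1) * (n - 1), b - 1, (b - 1) * (n - 1),
           (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1)),
    stringsAsFactors = FALSE)

  .anova_table(decomp, method = "rm_anova_2within")
}

# assemble F tests + effect sizes from a decomposition with df column
.anova_table <- function(decomp, method) {
  etas <- eta_squared(decomp)
  eff <- decomp[!decomp$is_error, , drop = FALSE]
  rows <- lapply(seq_len(nrow(eff)), function(i) {
    e <- eff[i, ]
    j <- match(e$error_term, decomp$term)
    ms_eff <- e$ss / e$df
    ms_err <- decomp$ss[j] / decomp$df[j]
    Fv <- ms_eff / ms_err
    data.frame(effect = e$term, df1 = e$df, df2 = decomp$df[j],
               ss = e$ss, ss_error = decomp$ss[j],
               statistic = Fv,
               p = stats::pf(Fv, e$df, decomp$df[j], lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  table$eta_g <- etas$eta_g[match(table$effect, etas$term)]
  table$eta_p <- etas$eta_p[match(table$effect, etas$term)]
  structure(list(table = table, decomp = decomp, method = method),
            class = "vwm_anova")
}

#' @export
print.vwm_anova <- function(x, ...) {
  cat(x$method, "\n")
  tb <- x$table
  tb$statistic <- round(tb$statistic, 2)
  tb$p <- signif(tb$p, 3)
  tb$eta_g <- round(tb$eta_g, 3)
  tb$eta_p <- round(tb$eta_p, 3)
  print(tb[, c("effect", "df1", "df2", "statistic", "p", "eta_g", "eta_p")],
        row.names = FALSE)
  invisible(x)
}
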
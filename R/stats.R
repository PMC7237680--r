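# Inferential statistics on cohort blink rates: normality checks, the
# overall between-group comparison, the scene-type x task-group mixed
# ANOVA interaction, and per-timescale paired tests with Bonferroni-Holm
# step-down correction.

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return tibble `test, statistic, df, p_value, n`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort("normality_check: need 3 <= n <= 5000",
          class = "blinkengage_validation_error")
  }
  if (sd(values) == 0) {
    abort("normality_check: constant input",
          class = "blinkengage_validation_error")
  }
  sw <- shapiro.test(values)
  tibble(test = "shapiro_wilk", statistic = unname(sw$statistic),
         df = n, p_value = sw$p.value, n = n)
}

#' Two-sample t-test on overall blink rates
#'
#' Pooled-variance two-sample t (df = n1 + n2 - 2), comparing session
#' blink rates between task groups.
#'
#' @param values numeric vector of per-participant rates.
#' @param group two-level grouping vector.
#' @return tibble `test, statistic, df, p_value, n`.
#' @export
group_t_test <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    abort("group_t_test: need exactly two groups",
          class = "blinkengage_validation_error")
  }
  tt <- t.test(values ~ group, var.equal = TRUE)
  tibble(test = "two_sample_t", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         n = length(values))
}

#' Scene-type x task-group interaction (mixed ANOVA)
#'
#' Mixed ANOVA with scene type (land vs water) as a within-subjects factor
#' and task group as a between-subjects factor. With one two-level
#' within factor, the interaction F equals the square of the pooled
#' two-sample t comparing the within-participant differences
#' (land - water) between groups; both routes are computed and asserted
#' equal, and the t-route statistics are returned with df (1, n - 2).
#'
#' @param bpm_land,bpm_water paired per-participant rates.
#' @param group task-group labels.
#' @return tibble `test, statistic (F), df1, df2, p_value, n`.
#' @export
interaction_anova <- function(bpm_land, bpm_water, group) {
  if (length(bpm_land) != length(bpm_water) ||
      length(bpm_land) != length(group)) {
    abort("interaction_anova: inputs must have equal length",
          class = "blinkengage_validation_error")
  }
  if (anyNA(bpm_land) || anyNA(bpm_water)) {
    abort("interaction_anova: incomplete pair",
          class = "blinkengage_validation_error")
  }
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2 || min(table(group)) < 2) {
    abort("interaction_anova: need two groups with >= 2 participants each",
          class = "blinkengage_validation_error")
  }
  diffs <- bpm_land - bpm_water
  n <- length(diffs)
  m <- tapply(diffs, group, mean)
  ss <- tapply(diffs, group, function(v) sum((v - mean(v))^2))
  nn <- tapply(diffs, group, length)
  sp2 <- sum(ss) / (n - 2)               # pooled variance
  if (sp2 == 0) {
    # degenerate: identical within-group differences
    f_t2 <- if (m[1] == m[2]) 0 else Inf
  } else {
    t_stat <- (m[1] - m[2]) / sqrt(sp2 * (1 / nn[1] + 1 / nn[2]))
    f_t2 <- unname(t_stat)^2
  }

  # independent route: aov on the long within/between layout (skipped in
  # the zero-variance degenerate case, where aov's F is undefined)
  if (sp2 > 0) {
  long <- data.frame(
    pid = factor(rep(seq_len(n), 2)),
    scene = factor(rep(c("land", "water"), each = n)),
    grp = factor(rep(group, 2)),
    bpm = c(bpm_land, bpm_water)
  )
  av <- summary(aov(bpm ~ scene * grp + Error(pid / scene), data = long))
  within_tab <- av[["Error: pid:scene"]][[1]]
  f_aov <- within_tab["scene:grp", "F value"]
  if (!isTRUE(abs(f_aov - f_t2) <= 1e-6 * max(1, f_t2))) {
    abort("interaction_anova: aov and t^2 routes disagree (internal error)",
          class = "blinkengage_runtime_error")
  }
  }
  tibble(test = "scene_by_group_interaction", statistic = f_t2,
         df1 = 1, df2 = n - 2,
         p_value = pf(f_t2, 1, n - 2, lower.tail = FALSE), n = n)
}

#' Paired tests of task-relevant vs task-irrelevant rates per timescale
#'
#' One paired t-test per alternation condition (relevant minus irrelevant
#' bpm), with Bonferroni-Holm step-down correction across conditions.
#' Conditions with zero-variance differences are recorded with NA
#' statistics (logged) and do not shrink the correction family.
#'
#' @param rates_by_condition output of
#'   `scene_rates(..., by_condition = TRUE)`.
#' @return tibble `condition_s, statistic, df, p_value, p_corrected, n`,
#'   ordered by condition.
#' @export
timescale_paired_tests <- function(rates_by_condition) {
  need <- c("participant_id", "condition_s", "bpm_relevant",
            "bpm_irrelevant")
  check_cols(rates_by_condition, need, "rates_by_condition")
  conds <- sort(unique(rates_by_condition$condition_s))
  stat <- df <- p <- rep(NA_real_, length(conds))
  nn <- integer(length(conds))
  for (k in seq_along(conds)) {
    rc <- rates_by_condition[rates_by_condition$condition_s == conds[k], ]
    if (anyNA(rc$bpm_relevant) || anyNA(rc$bpm_irrelevant)) {
      abort(sprintf("timescale_paired_tests: incomplete pairs at %g s",
                    conds[k]),
            class = "blinkengage_validation_error")
    }
    d <- rc$bpm_relevant - rc$bpm_irrelevant
    nn[k] <- length(d)
    if (sd(d) == 0) {
      warn(sprintf(
        "timescale_paired_tests: zero-variance differences at %g s; skipped",
        conds[k]))
      next
    }
    tt <- t.test(rc$bpm_relevant, rc$bpm_irrelevant, paired = TRUE)
    stat[k] <- unname(tt$statistic)
    df[k] <- unname(tt$parameter)
    p[k] <- tt$p.value
  }
  p_corr <- rep(NA_real_, length(conds))
  ok <- !is.na(p)
  # Holm over the attempted family (skipped tests keep the family size)
  if (any(ok)) {
    p_corr[ok] <- p.adjust(p[ok], method = "holm", n = length(conds))
  }
  tibble(condition_s = conds, statistic = stat, df = df, p_value = p,
         p_corrected = p_corr, n = nn)
}
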
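# Classification strength via kernel-density likelihood ratios. For each
# alternation condition, a Gaussian KDE of the content-aware metric is
# estimated per task group; a participant's likelihood ratio is the
# density of their metric under their correct group divided by its density
# under the incorrect group. LR > 1 means the participant fits their
# assigned group better than the other.

#' Gaussian kernel density estimate of one group's metric distribution
#'
#' @param values the group's metric values (>= 2).
#' @param bandwidth kernel SD; default Silverman's rule-of-thumb
#'   ([stats::bw.nrd0()]).
#' @return a vectorized density function `f(x)` with attribute
#'   `bandwidth`; integrates to 1.
#' @export
group_pdf <- function(values, bandwidth = NULL) {
  if (length(values) < 1) {
    abort("group_pdf: need at least one value",
          class = "blinkengage_validation_error")
  }
  if (is.null(bandwidth)) {
    if (length(values) < 2) {
      abort("group_pdf: need >= 2 values for automatic bandwidth",
            class = "blinkengage_validation_error")
    }
    bandwidth <- bw.nrd0(values)
  }
  if (!isTRUE(bandwidth > 0)) {
    abort("group_pdf: bandwidth must be > 0 (identical values?)",
          class = "blinkengage_validation_error")
  }
  f <- function(x) {
    vapply(x, function(xi) mean(dnorm(xi, mean = values, sd = bandwidth)),
           numeric(1))
  }
  attr(f, "bandwidth") <- bandwidth
  f
}

#' Likelihood ratio of group membership
#'
#' `lr = pdf_correct(metric) / pdf_incorrect(metric)`, with both densities
#' floored at `floor` so the ratio stays finite.
#'
#' @param metric the participant's content-aware metric.
#' @param pdf_correct,pdf_incorrect density functions (see [group_pdf()]).
#' @param floor density floor guarding zeros.
#' @return list with `metric`, `lr`, `log_lr` (natural log).
#' @export
likelihood_ratio <- function(metric, pdf_correct, pdf_incorrect,
                             floor = 1e-12) {
  num <- max(pdf_correct(metric), floor)
  den <- max(pdf_incorrect(metric), floor)
  # log as a difference so swapping numerator/denominator negates exactly
  list(metric = metric, lr = num / den, log_lr = log(num) - log(den))
}

#' Per-participant classification strength for each condition
#'
#' For every alternation condition, estimates the two group PDFs of the
#' content-aware metric and computes each participant's likelihood ratio.
#' By default a participant's own metric is excluded from their correct
#' group's density (leave-one-out, guarding against self-inflation); the
#' same exclusion applies to whichever group sample contains the
#' participant, so swapping correct/incorrect roles negates `log_lr`
#' exactly. Set `exclude_self = FALSE` for the inclusive variant.
#'
#' @param rates_by_condition output of
#'   `scene_rates(..., by_condition = TRUE)`.
#' @param bandwidth fixed kernel SD, or `NULL` for Silverman's rule
#'   computed per group and condition (on the full group sample, so a
#'   common bandwidth is used for every participant).
#' @param exclude_self leave the participant's own metric out of their
#'   group's density.
#' @param floor density floor.
#' @param swap_groups compute the ratio with correct/incorrect roles
#'   swapped (diagnostic).
#' @return tibble `participant_id, group, condition_s, bpm_condition,
#'   metric, lr, log_lr`.
#' @export
classification_strength <- function(rates_by_condition, bandwidth = NULL,
                                    exclude_self = TRUE, floor = 1e-12,
                                    swap_groups = FALSE) {
  need <- c("participant_id", "group", "condition_s", "bpm_session", "metric")
  check_cols(rates_by_condition, need, "rates_by_condition")
  rows <- vector("list", 0L)
  for (cond in sort(unique(rates_by_condition$condition_s))) {
    rc <- rates_by_condition[rates_by_condition$condition_s == cond, ]
    by_group <- split(rc$metric, rc$group)
    if (length(by_group) != 2) {
      abort("classification_strength: need both groups in every condition",
            class = "blinkengage_validation_error")
    }
    bw_group <- lapply(by_group, function(v) {
      if (is.null(bandwidth)) bw.nrd0(v) else bandwidth
    })
    for (i in seq_len(nrow(rc))) {
      own <- rc$group[i]
      other <- setdiff(names(by_group), own)
      own_vals <- by_group[[own]]
      if (exclude_self) {
        drop_idx <- match(rc$metric[i], own_vals)
        own_vals <- own_vals[-drop_idx]
      }
      pdf_own <- group_pdf(own_vals, bandwidth = bw_group[[own]])
      pdf_other <- group_pdf(by_group[[other]],
                             bandwidth = bw_group[[other]])
      res <- if (swap_groups) {
        likelihood_ratio(rc$metric[i], pdf_other, pdf_own, floor)
      } else {
        likelihood_ratio(rc$metric[i], pdf_own, pdf_other, floor)
      }
      rows[[length(rows) + 1L]] <- tibble(
        participant_id = rc$participant_id[i],
        group = own,
        condition_s = cond,
        bpm_condition = rc$bpm_session[i],
        metric = rc$metric[i],
        lr = res$lr,
        log_lr = res$log_lr
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Regression suite relating blink rate to classification strength
#'
#' Least-squares fits of `y` (log likelihood ratio) on `x` (the
#' participant's blink rate during a condition): polynomials of degree 1-3
#' and the exponential model `y = a * exp(b * x)` by nonlinear least
#' squares (initialized from a log-linear fit on shifted-positive y).
#' P-values are for the overall fit against the intercept-only model and
#' are Bonferroni-corrected for `n_comparisons` conditions.
#'
#' @param x,y numeric vectors (>= 5 points, more for higher degrees).
#' @param n_comparisons Bonferroni family size (default 13, one per
#'   alternation condition).
#' @return tibble `form, r_squared, p_value, p_bonferroni, converged` with
#'   coefficient vectors in the list column `coefficients`.
#' @export
strength_regressions <- function(x, y, n_comparisons = 13) {
  if (sd(x) == 0) {
    abort("strength_regressions: constant x (singular design)",
          class = "blinkengage_validation_error")
  }
  forms <- c("linear", "quadratic", "cubic", "exponential")
  n <- length(x)
  ss_tot <- sum((y - mean(y))^2)
  overall_p <- function(ss_res, n_par) {
    df1 <- n_par - 1; df2 <- n - n_par
    if (df2 <= 0) return(NA_real_)
    if (ss_res <= 0) return(0)    # interpolating fit
    f <- ((ss_tot - ss_res) / df1) / (ss_res / df2)
    pf(f, df1, df2, lower.tail = FALSE)
  }
  rows <- vector("list", length(forms))
  for (k in seq_along(forms)) {
    form <- forms[k]
    if (form != "exponential") {
      deg <- match(form, c("linear", "quadratic", "cubic"))
      if (n < deg + 2) {
        abort(sprintf("strength_regressions: need >= %d points for %s fit",
                      deg + 2, form),
              class = "blinkengage_validation_error")
      }
      fit <- lm(y ~ poly(x, deg, raw = TRUE))
      ss_res <- sum(resid(fit)^2)
      r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
      p <- overall_p(ss_res, deg + 1)
      rows[[k]] <- tibble(form = form, r_squared = r2, p_value = p,
                          p_bonferroni = pmin(1, n_comparisons * p),
                          converged = TRUE,
                          coefficients = list(unname(coef(fit))))
    } else {
      ys <- y - min(y) + 1e-6 * max(1, diff(range(y)))
      init <- tryCatch({
        lf <- lm(log(ys) ~ x)
        list(a = exp(coef(lf)[[1]]), b = coef(lf)[[2]])
      }, error = function(e) list(a = mean(y), b = 0))
      if (!is.finite(init$a) || !is.finite(init$b)) {
        init <- list(a = mean(y), b = 0)
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(b * x), start = init,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) {
        rows[[k]] <- tibble(form = form, r_squared = NA_real_,
                            p_value = NA_real_, p_bonferroni = NA_real_,
                            converged = FALSE,
                            coefficients = list(c(NA_real_, NA_real_)))
      } else {
        ss_res <- sum(resid(fit)^2)
        r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
        p <- overall_p(ss_res, 2)
        rows[[k]] <- tibble(form = form, r_squared = r2, p_value = p,
                            p_bonferroni = pmin(1, n_comparisons * p),
                            converged = TRUE,
                            coefficients = list(unname(coef(fit))))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Deming (errors-in-variables) regression
#'
#' Closed-form line fit accounting for measurement error in both
#' variables, with `variance_ratio` = (error variance of y) / (error
#' variance of x). `variance_ratio = 1` gives orthogonal regression.
#'
#' @param x,y numeric vectors (>= 3 points).
#' @param variance_ratio positive error-variance ratio.
#' @return list with `slope` and `intercept`.
#' @export
deming_fit <- function(x, y, variance_ratio = 1) {
  if (length(x) < 3 || length(x) != length(y)) {
    abort("deming_fit: need >= 3 paired points",
          class = "blinkengage_validation_error")
  }
  if (!isTRUE(variance_ratio > 0)) {
    abort("deming_fit: variance_ratio must be > 0",
          class = "blinkengage_validation_error")
  }
  sxx <- var(x); syy <- var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0) {
    abort("deming_fit: zero variance in both axes",
          class = "blinkengage_validation_error")
  }
  if (sxy == 0) {
    abort("deming_fit: zero covariance; slope undefined",
          class = "blinkengage_validation_error")
  }
  lam <- variance_ratio
  slope <- (syy - lam * sxx +
              sqrt((syy - lam * sxx)^2 + 4 * lam * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}
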
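test_that("group pdfs are proper densities", {
  f1 <- group_pdf(0, bandwidth = 1)
  expect_equal(f1(0), 1 / sqrt(2 * pi), tolerance = 1e-12)

  fsym <- group_pdf(c(-3, 3), bandwidth = 0.8)
  xs <- seq(0.1, 5, by = 0.3)
  expect_equal(fsym(xs), fsym(-xs), tolerance = 1e-12)

  set.seed(2)
  f <- group_pdf(rnorm(10, 2, 1.5))
  bw <- attr(f, "bandwidth")
  grid <- stats::integrate(f, 2 - 10 * (1.5 + bw), 2 + 10 * (1.5 + bw),
                           rel.tol = 1e-9, subdivisions = 500)
  expect_equal(grid$value, 1, tolerance = 1e-6)
  expect_error(group_pdf(c(1, 1), bandwidth = 0),
               class = "blinkengage_validation_error")
})

test_that("likelihood ratios follow arithmetic and floor rules", {
  f4 <- function(x) rep(0.4, length(x))
  f1 <- function(x) rep(0.1, length(x))
  res <- likelihood_ratio(0, f4, f1)
  expect_equal(res$lr, 4.0)
  expect_equal(res$log_lr, log(4), tolerance = 1e-12)

  eq <- likelihood_ratio(0, f4, f4)
  expect_equal(eq$lr, 1.0)
  expect_equal(eq$log_lr, 0.0)

  zero <- function(x) rep(0, length(x))
  fl <- likelihood_ratio(0, f4, zero, floor = 1e-12)
  expect_equal(fl$lr, 0.4 / 1e-12)
  expect_true(is.finite(fl$log_lr))
})

test_that("swapping group roles negates log LR exactly; all LR positive", {
  co <- small_cohort(seed = 23, n_land = 4, n_water = 4,
                     conditions = c(5, 20))
  rc <- scene_rates(co$participants, co$events, co$schedules,
                    by_condition = TRUE)
  s1 <- classification_strength(rc)
  s2 <- classification_strength(rc, swap_groups = TRUE)
  expect_equal(s2$log_lr, -s1$log_lr, tolerance = 1e-12)
  expect_true(all(s1$lr > 0))

  # well-separated groups fit their own side: all lr > 1. A tight
  # baseline-rate spread keeps the two metric distributions disjoint
  # (at the default 6.7 bpm spread the groups overlap and boundary
  # members can legitimately fall below 1 under self-exclusion).
  co2 <- simulate_cohort(cohort_params(seed = 31, suppression_rho = 0.4,
                                       rate_sd_bpm = 1))
  rc2 <- scene_rates(co2$participants, co2$events, co2$schedules,
                     by_condition = TRUE)
  s3 <- classification_strength(rc2[rc2$condition_s == 20, ])
  expect_true(all(s3$lr > 1))
})

test_that("self-exclusion matches the single-kernel closed form at n = 2", {
  rc <- tibble::tibble(
    participant_id = c("A", "B", "C", "D"),
    group = rep(c("land_counter", "water_counter"), each = 2),
    condition_s = 5,
    bpm_session = c(10, 12, 11, 13),
    metric = c(-3, -1, 1, 3)
  )
  s <- classification_strength(rc, bandwidth = 1)
  # for participant A the self-excluded own-group density is the single
  # kernel centered at B's metric
  a <- s[s$participant_id == "A", ]
  own <- dnorm(-3, mean = -1, sd = 1)
  other <- mean(dnorm(-3, mean = c(1, 3), sd = 1))
  expect_equal(a$lr, own / other, tolerance = 1e-12)
})

test_that("regression suite recovers noiseless fits", {
  x <- seq(1, 12)
  fits_lin <- strength_regressions(x, 2 * x + 1)
  lin <- fits_lin[fits_lin$form == "linear", ]
  expect_equal(lin$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(lin$coefficients[[1]], c(1, 2), tolerance = 1e-8)

  fits_exp <- strength_regressions(x / 4, 3 * exp(0.5 * x / 4))
  ex <- fits_exp[fits_exp$form == "exponential", ]
  expect_true(ex$converged)
  expect_equal(ex$coefficients[[1]], c(3, 0.5), tolerance = 1e-6)
  expect_equal(ex$r_squared, 1.0, tolerance = 1e-9)

  expect_equal(fits_lin$p_bonferroni, pmin(1, 13 * fits_lin$p_value))
  expect_error(strength_regressions(rep(1, 10), rnorm(10)),
               class = "blinkengage_validation_error")
})

test_that("low-rate participants show weaker 1 s-condition classification strength", {
  # direction check: log LR increases with blink rate when scenes alternate
  # every second (short scenes starve low-rate participants of evidence)
  slopes <- p_vals <- numeric(6)
  for (s in seq_along(slopes)) {
    co <- simulate_cohort(cohort_params(seed = 600 + s),
                          conditions = c(1, 20))
    rc <- scene_rates(co$participants, co$events, co$schedules,
                      by_condition = TRUE)
    s1 <- classification_strength(rc[rc$condition_s == 1, ])
    fit <- strength_regressions(s1$bpm_condition, s1$log_lr)
    slopes[s] <- fit$coefficients[[match("linear", fit$form)]][2]
    p_vals[s] <- fit$p_value[match("linear", fit$form)]
  }
  expect_gte(sum(slopes > 0), 5)    # positive trend in the clear majority
})

test_that("deming regression is exact on lines and symmetric under swap", {
  x <- seq(0, 10); y <- 2 * x + 1
  fit <- deming_fit(x, y)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)

  set.seed(10)
  xn <- rnorm(40); yn <- xn + rnorm(40, 0, 0.5)
  f1 <- deming_fit(xn, yn)
  f2 <- deming_fit(yn, xn)
  expect_equal(f2$slope, 1 / f1$slope, tolerance = 1e-9)

  expect_error(deming_fit(rep(1, 5), rep(2, 5)),
               class = "blinkengage_validation_error")
})

test_that("deming regression corrects the attenuation of ordinary least squares", {
  set.seed(14)
  n <- 4000
  truth <- rnorm(n, 0, 2)
  x <- truth + rnorm(n)        # equal error variance on both axes
  y <- truth + rnorm(n)
  ols_slope <- coef(lm(y ~ x))[[2]]
  dem_slope <- deming_fit(x, y, variance_ratio = 1)$slope
  expect_lt(ols_slope, 0.9)                 # attenuated
  expect_equal(dem_slope, 1, tolerance = 0.05)
})
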
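test_that("make_schedules obeys the even-scene-count rule and envelope", {
  s1 <- make_schedules(120, 60, "land")
  expect_equal(nrow(s1), 2L)
  expect_equal(s1$category, c("land", "water"))
  expect_equal(s1$offset_s[2], 120)

  s2 <- make_schedules(120, 1, "water")
  expect_equal(nrow(s2), 120L)
  expect_equal(s2$category[1:3], c("water", "land", "water"))

  s3 <- make_schedules(120, 50, "land")   # floor(120/50) = 2 after even-rounding
  expect_equal(nrow(s3), 2L)
  expect_equal(max(s3$offset_s), 100)     # inside the 90-160.2 s envelope

  expect_error(make_schedules(120, 70), "cannot fit",
               class = "blinkengage_validation_error")
  # 13 canonical conditions all fit at the 160 s default
  s13 <- make_schedules(160)
  expect_equal(length(unique(s13$video_id)), 13L)
  expect_true(all(tapply(s13$offset_s, s13$video_id, max) >= 90))
})

test_that("baseline-rate draws honor bounds, degenerate SD, and the printed moments", {
  prof <- sample_cohort(cohort_params(seed = 5))
  expect_true(all(prof$lambda_bpm >= 2 & prof$lambda_bpm <= 26))
  expect_equal(nrow(prof), 21L)
  expect_equal(sum(prof$group == "land_counter"), 11L)
  expect_equal(sum(prof$parity == "attended_odd"), 11L)

  fixed <- sample_cohort(cohort_params(rate_sd_bpm = 0, seed = 5))
  expect_true(all(fixed$lambda_bpm == 12.6))

  # Oracle: numeric integration of the truncated-normal the generator draws
  # from must give the printed mean; the 10k sample mean must match both.
  x <- sample_baseline_rates(10000, cohort_params(seed = 12))
  sol <- blinkengage:::truncnorm_solve(12.6, 6.7, 2, 26)
  Z <- pnorm(26, sol$mu, sol$sigma) - pnorm(2, sol$mu, sol$sigma)
  oracle_mean <- stats::integrate(
    function(v) v * dnorm(v, sol$mu, sol$sigma) / Z, 2, 26)$value
  expect_equal(oracle_mean, 12.6, tolerance = 1e-6)
  expect_lt(abs(mean(x) - oracle_mean), 0.2)
  expect_error(
    sample_cohort(cohort_params(rate_sd_bpm = 20, seed = 1)),
    "infeasible", class = "blinkengage_validation_error")
})

test_that("simulated blink rates realize the dead-time-compensated targets", {
  sch <- make_schedules(160, 20, "land")
  count_rates <- function(rho, lambda, n_videos, seed) {
    prof <- list(group = "land_counter", lambda_bpm = lambda, rho = rho)
    set.seed(seed)
    rel <- irr <- 0; exp_rel <- exp_irr <- 0
    for (v in seq_len(n_videos)) {
      ev <- simulate_blinks(prof, sch)
      for (k in seq_len(nrow(sch))) {
        n_in <- sum(ev$onset_s >= sch$onset_s[k] & ev$onset_s < sch$offset_s[k])
        if (sch$category[k] == "land") {
          rel <- rel + n_in; exp_rel <- exp_rel + 20
        } else {
          irr <- irr + n_in; exp_irr <- exp_irr + 20
        }
      }
    }
    c(rel = 60 * rel / exp_rel, irr = 60 * irr / exp_irr)
  }
  # 10^4 simulated minutes split over the two categories
  n_videos <- ceiling(10000 * 60 / 160)
  r_null <- count_rates(rho = 1, lambda = 12, n_videos, seed = 21)
  se_null <- 60 * sqrt(12 / 60 * 5000 * 60) / (5000 * 60)
  expect_lt(abs(r_null["rel"] - r_null["irr"]), 3 * sqrt(2) * se_null)

  r_half <- count_rates(rho = 0.5, lambda = 12, n_videos, seed = 22)
  se6 <- 60 * sqrt(6 / 60 * 5000 * 60) / (5000 * 60)
  se18 <- 60 * sqrt(18 / 60 * 5000 * 60) / (5000 * 60)
  expect_lt(abs(r_half["rel"] - 6), 3 * se6)
  expect_lt(abs(r_half["irr"] - 18), 3 * se18)
})

test_that("session-level realized rate is rho-invariant and events never overlap", {
  sch <- make_schedules(160, 10, "land")
  session_bpm <- function(rho, seed) {
    prof <- list(group = "land_counter", lambda_bpm = 14, rho = rho)
    set.seed(seed)
    n <- 0
    for (v in 1:40) n <- n + nrow(simulate_blinks(prof, sch))
    60 * n / (40 * 160)
  }
  b1 <- session_bpm(1, 31); b2 <- session_bpm(0.4, 32)
  se <- 60 * sqrt(14 / 60 * 40 * 160) / (40 * 160)
  expect_lt(abs(b1 - b2), 4 * se)

  prof <- list(group = "land_counter", lambda_bpm = 25, rho = 0.3)
  ev <- simulate_blinks(prof, sch, seed = 9)
  expect_true(all(diff(ev$onset_s) > 0))
  expect_true(all(ev$onset_s[-1] >= head(ev$onset_s + ev$duration_s, -1)))
  expect_true(all(ev$duration_s >= 0.15 & ev$duration_s <= 0.4))
})

test_that("cohort simulation is deterministic in the seed and suppression shows in every participant", {
  a <- simulate_cohort(cohort_params(seed = 40), conditions = c(5, 20))
  b <- simulate_cohort(cohort_params(seed = 40), conditions = c(5, 20))
  expect_identical(a$events, b$events)
  expect_identical(a$profiles, b$profiles)
  c2 <- simulate_cohort(cohort_params(seed = 41), conditions = c(5, 20))
  expect_false(identical(a$events, c2$events))

  # task-consistent sign of the content-aware metric across whole cohorts
  n_bad <- 0
  for (s in 1:8) {
    co <- simulate_cohort(cohort_params(seed = 500 + s))
    r <- scene_rates(co$participants, co$events, co$schedules)
    n_bad <- n_bad + sum(r$bpm_relevant >= r$bpm_irrelevant)
  }
  expect_equal(n_bad, 0L)
})

test_that("rendered traces invert cleanly: occlusion runs and truncation", {
  tr0 <- render_pupil_trace(tibble::tibble(onset_s = numeric(0),
                                           duration_s = numeric(0)),
                            duration_s = 2, noise_sd = 0)
  expect_true(all(tr0$valid))
  expect_equal(length(unique(tr0$diameter)), 1L)

  tr1 <- render_pupil_trace(tibble::tibble(onset_s = 5, duration_s = 0.3),
                            duration_s = 10, noise_sd = 0)
  runs <- rle(!tr1$valid)
  expect_equal(sum(runs$values), 1L)       # exactly one invalid run
  inv_t <- tr1$t[!tr1$valid]
  expect_true(min(inv_t) >= 5 && max(inv_t) <= 5.3)

  expect_warning(
    render_pupil_trace(tibble::tibble(onset_s = 9.9, duration_s = 0.3),
                       duration_s = 10, noise_sd = 0),
    "truncated")
})
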
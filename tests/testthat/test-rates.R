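test_that("bpm is count over exposure with half-open windows", {
  ev <- tibble::tibble(onset_s = c(1, 5, 20))
  expect_equal(bpm(ev, cbind(0, 30)), 6.0)
  expect_equal(bpm(tibble::tibble(onset_s = numeric(0)), cbind(0, 30)), 0)
  # onset exactly at a window's end boundary is not counted there
  expect_equal(bpm(tibble::tibble(onset_s = 30), cbind(0, 30)), 0)
  expect_equal(bpm(tibble::tibble(onset_s = 30), cbind(30, 60)), 2)
  expect_error(bpm(ev, cbind(c(0, 5), c(10, 15))), "disjoint",
               class = "blinkengage_validation_error")
})

test_that("pooled bpm differs from the mean of per-window rates on unequal windows", {
  ev <- tibble::tibble(onset_s = c(1, 2, 3, 50))
  w <- cbind(c(0, 10), c(10, 70))      # 10 s and 60 s windows
  pooled <- bpm(ev, w)
  expect_equal(pooled, 60 * 4 / 70)
  per_window <- mean(c(bpm(ev, cbind(0, 10)), bpm(ev, cbind(10, 70))))
  expect_false(isTRUE(all.equal(pooled, per_window)))
})

test_that("scene rates pool counts by category and relabel by task group", {
  sch <- toy_schedule()                          # land 0-60, water 60-120
  parts <- toy_participants()
  parts$parity[2] <- "attended_even"             # both watch the land-first set
  ev <- dplyr::bind_rows(
    toy_events("P01", "v60_l", c(10, 50, 70, 80, 90, 110)),  # 2 land, 4 water
    toy_events("P02", "v60_l", c(10, 70))
  )
  r <- scene_rates(parts, ev, sch)
  p1 <- r[r$participant_id == "P01", ]
  expect_equal(p1$bpm_land, 2.0)
  expect_equal(p1$bpm_water, 4.0)
  expect_equal(p1$metric, -2.0)
  expect_equal(p1$bpm_relevant, 2.0)             # land counter
  p2 <- r[r$participant_id == "P02", ]
  expect_equal(p2$bpm_relevant, p2$bpm_water)    # water counter relabeling
  expect_equal(p2$metric, 0.0)                   # symmetric stream
  expect_error(scene_rates(parts, toy_events("P01", "nope", 1), sch),
               "schedule", class = "blinkengage_validation_error")
})

test_that("simulated participants blink less during task-relevant scenes", {
  co <- simulate_cohort(cohort_params(seed = 77))   # ~29.7 min exposure
  r <- scene_rates(co$participants, co$events, co$schedules)
  expect_true(all(r$bpm_relevant < r$bpm_irrelevant))
})

test_that("interval vectors bin onsets, drop partial tails, keep fixed order", {
  sch <- tibble::tibble(video_id = "v", condition_s = 5, scene_index = 1:2,
                        category = c("land", "water"),
                        onset_s = c(0, 5), offset_s = c(5, 10))
  ev <- toy_events("P01", "v", c(1, 2, 7))
  iv <- interval_vector(ev, sch, 5, "v")
  expect_equal(iv$bpm, c(24, 12))

  sch120 <- toy_schedule()
  iv10 <- interval_vector(toy_events("P01", "v60_l", numeric(0)),
                          sch120, 10, "v60_l")
  expect_equal(nrow(iv10), 12L)
  expect_true(all(iv10$bpm == 0))

  # interval 7 on a 120 s video: trailing 1 s bin [119, 120) dropped
  iv7 <- interval_vector(toy_events("P01", "v60_l", c(112.5, 119.5)),
                         sch120, 7, "v60_l")
  expect_equal(nrow(iv7), 17L)
  expect_equal(sum(iv7$bpm > 0), 1L)   # onset in the dropped tail not counted
})

test_that("exposure-weighted mean of interval rates equals session bpm without partial bins", {
  co <- small_cohort(seed = 3, conditions = c(15, 20))  # durations 150, 160
  pid <- co$participants$participant_id[1]
  vids <- blinkengage:::participant_videos(co$participants$group[1],
                                           co$participants$parity[1],
                                           co$schedules)
  iv <- interval_vector(co$events[co$events$participant_id == pid, ],
                        co$schedules, 5, vids)   # 5 divides both durations
  sess <- 60 * sum(co$events$participant_id == pid) / (150 + 160)
  expect_equal(mean(iv$bpm), sess, tolerance = 1e-9)
})

test_that("instantaneous rate conserves events and detects suppression", {
  one <- instantaneous_rate(list(c(12.3)), duration_s = 60, bandwidth_s = 1)
  expect_equal(sum(one$rate_bpm / 60) / 30, 1.0, tolerance = 1e-9)

  zero <- instantaneous_rate(list(numeric(0)), duration_s = 30)
  expect_true(all(zero$rate_bpm == 0))

  # two groups on a 5 s-alternation video: rate lower inside relevant scenes
  sch <- make_schedules(160, 5, "land")
  set.seed(42)
  ons <- lapply(1:30, function(i) {
    prof <- list(group = "land_counter", lambda_bpm = 14, rho = 0.5)
    simulate_blinks(prof, sch)$onset_s
  })
  rate <- instantaneous_rate(ons, duration_s = 160, bandwidth_s = 1)
  scene_of <- sch$category[findInterval(rate$t, sch$onset_s)]
  expect_lt(mean(rate$rate_bpm[scene_of == "land"]),
            mean(rate$rate_bpm[scene_of == "water"]))
})

test_that("feature matrices are aligned, labeled, and order independent", {
  co <- small_cohort(seed = 5)
  f <- build_features(co$participants, co$events, co$schedules, 5)
  expect_equal(nrow(f$x), 6L)
  expect_equal(ncol(f$x), (150 + 160) / 5)
  expect_s3_class(f$labels, "factor")
  expect_setequal(levels(f$labels), c("attended_odd", "attended_even"))

  perm <- sample(nrow(co$participants))
  f2 <- build_features(co$participants[perm, ], co$events, co$schedules, 5)
  expect_equal(f2$x, f$x[perm, ])
  expect_equal(as.character(f2$labels), as.character(f$labels)[perm])
})
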
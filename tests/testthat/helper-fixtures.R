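# Shared fixtures, built in code.

# Minimal valid one-video schedule: land 0-60, water 60-120 (condition 60).
toy_schedule <- function(video_id = "v60_l", first = "land") {
  second <- setdiff(c("land", "water"), first)
  tibble::tibble(
    video_id = video_id, condition_s = 60, scene_index = 1:2,
    category = c(first, second), onset_s = c(0, 60), offset_s = c(60, 120)
  )
}

toy_events <- function(pid, vid, onsets, durs = 0.2) {
  tibble::tibble(participant_id = pid, video_id = vid,
                 onset_s = onsets,
                 duration_s = rep_len(durs, length(onsets)))
}

toy_participants <- function() {
  tibble::tibble(
    participant_id = c("P01", "P02"),
    group = c("land_counter", "water_counter"),
    parity = c("attended_odd", "attended_odd")
  )
}

# Small fast cohort used where the full 21-participant default is overkill.
small_cohort <- function(seed = 1, n_land = 3, n_water = 3,
                         rho = 0.5, conditions = c(15, 20)) {
  simulate_cohort(
    cohort_params(n_land = n_land, n_water = n_water,
                  suppression_rho = rho, seed = seed),
    target_duration_s = 160, conditions = conditions
  )
}

expect_tibble_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
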
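# Blink-rate summaries. All rates are blinks per minute (bpm): onset count
# over exposure, scaled to one minute. Category rates pool counts over
# total category exposure (never a mean of per-scene rates, which is
# unstable for 1 s scenes). Blink membership is by onset under the
# half-open [start, end) convention.

#' Blinks per minute over a set of windows
#'
#' `60 * count(onsets in any window) / total window seconds`, with window
#' membership half-open: an onset exactly at a window's end boundary is not
#' counted in that window.
#'
#' @param events tibble with column `onset_s` (durations, if present, are
#'   ignored: rate is an onset rate).
#' @param windows two-column data frame or matrix of `[start_s, end_s)`
#'   windows; must be pairwise disjoint with positive total length.
#' @return blink rate in blinks/minute.
#' @export
bpm <- function(events, windows) {
  w <- as.matrix(windows)
  if (ncol(w) != 2) {
    abort("bpm: windows must have two columns (start_s, end_s)",
          class = "blinkengage_validation_error")
  }
  w <- w[order(w[, 1]), , drop = FALSE]
  if (any(w[, 2] <= w[, 1])) {
    abort("bpm: windows must have end_s > start_s",
          class = "blinkengage_validation_error")
  }
  if (nrow(w) > 1 && any(w[-1, 1] < w[-nrow(w), 2])) {
    abort("bpm: windows must be disjoint",
          class = "blinkengage_validation_error")
  }
  exposure <- sum(w[, 2] - w[, 1])
  if (exposure <= 0) {
    abort("bpm: zero exposure", class = "blinkengage_validation_error")
  }
  count <- 0L
  for (k in seq_len(nrow(w))) {
    count <- count + sum(in_window(events$onset_s, w[k, 1], w[k, 2]))
  }
  60 * count / exposure
}

# Video set a participant saw: all videos whose first scene matches the
# participant's counterbalance assignment (implied by group and parity).
participant_videos <- function(group, parity, schedules) {
  rel <- relevant_category(group)
  first_cat <- if (parity == "attended_odd") rel else
    setdiff(SCENE_CATEGORIES, rel)
  firsts <- schedules[schedules$scene_index == 1, ]
  vids <- firsts$video_id[firsts$category == first_cat]
  if (!length(vids)) {
    abort(sprintf("no scheduled videos open with a %s scene", first_cat),
          class = "blinkengage_validation_error")
  }
  sort(vids)
}

#' Per-participant scene-category blink rates
#'
#' For each participant: mean blinks per minute over the entire viewing
#' session, over all land scenes, and over all water scenes, pooled across
#' composite videos (total onsets over total exposure per category);
#' `bpm_relevant`/`bpm_irrelevant` relabel the land/water rates by the
#' participant's task group, and `metric = bpm_land - bpm_water` is the
#' content-aware classification input. With `by_condition = TRUE` the same
#' quantities are computed separately per alternation condition (plus the
#' participant's overall rate during that condition's video), as used by
#' the timescale and likelihood-ratio analyses.
#'
#' @param participants,events,schedules domain tables.
#' @param by_condition compute per alternation condition instead of pooled.
#' @return tibble with one row per participant (or participant x condition).
#' @export
scene_rates <- function(participants, events, schedules,
                        by_condition = FALSE) {
  validate_participants(participants)
  missing_sch <- setdiff(unique(events$video_id), schedules$video_id)
  if (length(missing_sch)) {
    abort(sprintf("scene_rates: no schedule for video(s): %s",
                  paste(missing_sch, collapse = ", ")),
          class = "blinkengage_validation_error")
  }
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    grp <- participants$group[i]
    vids <- participant_videos(grp, participants$parity[i], schedules)
    ev <- events[events$participant_id == pid, ]
    sch <- schedules[schedules$video_id %in% vids, ]
    conds <- if (by_condition) sort(unique(sch$condition_s)) else NA
    for (cond in conds) {
      sub <- if (by_condition) sch[sch$condition_s == cond, ] else sch
      wl <- sub[sub$category == "land", c("onset_s", "offset_s", "video_id")]
      ww <- sub[sub$category == "water", c("onset_s", "offset_s", "video_id")]
      count_in <- function(w) {
        tot <- 0L
        for (vid in unique(w$video_id)) {
          wv <- w[w$video_id == vid, ]
          evv <- ev[ev$video_id == vid, ]
          for (k in seq_len(nrow(wv))) {
            tot <- tot + sum(in_window(evv$onset_s, wv$onset_s[k],
                                       wv$offset_s[k]))
          }
        }
        tot
      }
      exp_l <- sum(wl$offset_s - wl$onset_s)
      exp_w <- sum(ww$offset_s - ww$onset_s)
      n_l <- count_in(wl); n_w <- count_in(ww)
      bpm_land <- 60 * n_l / exp_l
      bpm_water <- 60 * n_w / exp_w
      bpm_session <- 60 * (n_l + n_w) / (exp_l + exp_w)
      rel_is_land <- relevant_category(grp) == "land"
      rows[[length(rows) + 1L]] <- tibble(
        participant_id = pid,
        group = grp,
        condition_s = if (by_condition) cond else NA_real_,
        bpm_session = bpm_session,
        bpm_land = bpm_land,
        bpm_water = bpm_water,
        bpm_relevant = if (rel_is_land) bpm_land else bpm_water,
        bpm_irrelevant = if (rel_is_land) bpm_water else bpm_land,
        metric = bpm_land - bpm_water
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!by_condition) out$condition_s <- NULL
  out
}

#' Interval-averaged blink-rate vector (content-unaware features)
#'
#' Average blink rates during consecutive intervals of fixed length within
#' each composite video (bins `[k*interval_s, (k+1)*interval_s)` from video
#' onset, trailing partial bin dropped), concatenated across videos in
#' fixed order of alternation condition.
#'
#' @param events one participant's events tibble.
#' @param schedules schedules tibble covering `video_ids`.
#' @param interval_s interval length in seconds (1--10).
#' @param video_ids the participant's video set; ordered internally by
#'   condition then id.
#' @return tibble `video_id, condition_s, bin_index, bpm`.
#' @export
interval_vector <- function(events, schedules, interval_s, video_ids) {
  if (!(interval_s %in% 1:10)) {
    abort("interval_vector: interval_s must be in 1..10",
          class = "blinkengage_validation_error")
  }
  info <- schedules[schedules$video_id %in% video_ids, ]
  vdur <- dplyr::summarise(
    dplyr::group_by(info, .data$video_id, .data$condition_s),
    duration = max(.data$offset_s), .groups = "drop")
  vdur <- dplyr::arrange(vdur, .data$condition_s, .data$video_id)
  rows <- vector("list", nrow(vdur))
  for (k in seq_len(nrow(vdur))) {
    nbin <- floor(vdur$duration[k] / interval_s)
    ons <- events$onset_s[events$video_id == vdur$video_id[k]]
    counts <- if (nbin > 0) {
      idx <- floor(ons / interval_s) + 1
      tabulate(idx[idx >= 1 & idx <= nbin & ons < nbin * interval_s],
               nbins = nbin)
    } else integer(0)
    rows[[k]] <- tibble(
      video_id = vdur$video_id[k],
      condition_s = vdur$condition_s[k],
      bin_index = seq_len(nbin),
      bpm = 60 * counts / interval_s
    )
  }
  dplyr::bind_rows(rows)
}

#' Smoothed instantaneous group blink rate
#'
#' Per-frame (30 Hz) blink-onset counts, averaged across participants,
#' convolved with a Gaussian kernel and scaled to blinks/minute. The kernel
#' mass truncated at the trace edges is renormalized per event so that the
#' time integral of the rate equals the mean blink count per participant
#' (rate conservation).
#'
#' @param onset_lists list of numeric vectors, one per participant, of
#'   blink onsets in seconds.
#' @param duration_s video duration in seconds.
#' @param bandwidth_s Gaussian kernel SD in seconds (default 1).
#' @param frame_hz frame rate of the output series.
#' @return tibble `t, rate_bpm`.
#' @export
instantaneous_rate <- function(onset_lists, duration_s, bandwidth_s = 1,
                               frame_hz = 30) {
  if (bandwidth_s <= 0) {
    abort("instantaneous_rate: bandwidth_s must be > 0",
          class = "blinkengage_validation_error")
  }
  n_frames <- floor(duration_s * frame_hz)
  counts <- numeric(n_frames)
  for (ons in onset_lists) {
    idx <- floor(ons * frame_hz) + 1
    idx <- idx[idx >= 1 & idx <= n_frames]
    counts <- counts + tabulate(idx, nbins = n_frames)
  }
  counts <- counts / length(onset_lists)
  r <- ceiling(4 * bandwidth_s * frame_hz)
  kern <- dnorm(seq(-r, r), sd = bandwidth_s * frame_hz)
  kern <- kern / sum(kern)
  # renormalize each frame's kernel by the mass remaining inside the trace
  ones <- rep(1, n_frames)
  inside_mass <- conv_same(ones, kern)
  smoothed <- conv_same(counts / inside_mass, kern)
  tibble(
    t = (seq_len(n_frames) - 0.5) / frame_hz,
    rate_bpm = smoothed * frame_hz * 60
  )
}

# 'same'-mode convolution with a centered symmetric kernel.
conv_same <- function(x, kern) {
  r <- (length(kern) - 1) / 2
  full <- stats::convolve(x, rev(kern), type = "open")
  full[(r + 1):(r + length(x))]
}

#' Content-unaware feature matrix
#'
#' One row per participant: their interval-averaged blink-rate vector
#' concatenated across composite videos (see [interval_vector()]), plus
#' attended-scene parity labels. All participants must yield equal-length
#' vectors.
#'
#' @param participants,events,schedules domain tables.
#' @param interval_s interval length in seconds (1--10).
#' @return list with `x` (numeric matrix, rownames = participant ids) and
#'   `labels` (factor of parity labels, levels `attended_odd`,
#'   `attended_even`).
#' @export
build_features <- function(participants, events, schedules, interval_s) {
  validate_participants(participants)
  vecs <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    vids <- participant_videos(participants$group[i],
                               participants$parity[i], schedules)
    iv <- interval_vector(events[events$participant_id == pid, ],
                          schedules, interval_s, vids)
    vecs[[i]] <- iv$bpm
  }
  lens <- lengths(vecs)
  if (length(unique(lens)) > 1) {
    bad <- participants$participant_id[which(lens != median(lens))[1]]
    abort(sprintf("build_features: feature length mismatch for participant '%s'",
                  bad),
          class = "blinkengage_validation_error")
  }
  x <- do.call(rbind, vecs)
  rownames(x) <- participants$participant_id
  list(x = x,
       labels = factor(participants$parity, levels = PARITY_LABELS))
}
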
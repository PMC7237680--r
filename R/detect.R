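# Blink detection from pupillometry: pupil occlusion is signalled by a
# rapid drop in measured pupil diameter and by vertical displacement of the
# pupil center as the lid closes. Detection runs at 30 Hz, after the 60 Hz
# recordings are down-sampled to the stimulus frame rate.

#' Blink-detector parameters
#'
#' @param diameter_drop_rate minimum fractional diameter decrease per sample
#'   (relative to the local open-pupil baseline) that opens a blink
#'   candidate. Default 0.30/sample at 30 Hz.
#' @param center_y_disp minimum vertical pupil-center displacement, in units
#'   of the baseline center-y SD, required for a tracking dropout to count
#'   as occlusion rather than track loss.
#' @param min_dur_s,max_dur_s admissible blink-duration range in seconds;
#'   candidates outside it are discarded (short dropouts and long track
#'   losses are not blinks).
#' @param merge_gap_s adjacent candidates closer than this gap are merged
#'   (partial re-openings within one blink).
#' @return validated list of class `detector_params`.
#' @export
detector_params <- function(diameter_drop_rate = 0.30, center_y_disp = 2.0,
                            min_dur_s = 0.05, max_dur_s = 1.0,
                            merge_gap_s = 0.05) {
  p <- list(diameter_drop_rate = diameter_drop_rate,
            center_y_disp = center_y_disp,
            min_dur_s = min_dur_s, max_dur_s = max_dur_s,
            merge_gap_s = merge_gap_s)
  if (!(p$min_dur_s > 0 && p$min_dur_s < p$max_dur_s)) {
    abort("detector_params: need 0 < min_dur_s < max_dur_s",
          class = "blinkengage_validation_error")
  }
  if (p$merge_gap_s < 0) {
    abort("detector_params: merge_gap_s must be >= 0",
          class = "blinkengage_validation_error")
  }
  class(p) <- "detector_params"
  p
}

#' Down-sample a 60 Hz pupil trace to 30 Hz
#'
#' Consecutive sample pairs are averaged for `diameter` and `center_y`;
#' the output sample is valid only if both inputs were (logical AND). An
#' odd trailing sample is dropped with a warning.
#'
#' @param trace a [pupil_trace()] at 60 Hz.
#' @return a [pupil_trace()] at 30 Hz.
#' @export
downsample_trace <- function(trace) {
  rate <- attr(trace, "sample_rate_hz")
  if (is.null(rate) || abs(rate - 60) > 1e-6) {
    abort("downsample_trace: trace must be sampled at 60 Hz",
          class = "blinkengage_validation_error")
  }
  n <- nrow(trace)
  if (n %% 2L == 1L) {
    warn("downsample_trace: odd sample count; dropping final sample")
    n <- n - 1L
  }
  i1 <- seq(1L, n, by = 2L); i2 <- i1 + 1L
  pupil_trace(
    t = (trace$t[i1] + trace$t[i2]) / 2,
    diameter = (trace$diameter[i1] + trace$diameter[i2]) / 2,
    center_y = (trace$center_y[i1] + trace$center_y[i2]) / 2,
    valid = trace$valid[i1] & trace$valid[i2],
    sample_rate_hz = 30
  )
}

# Median of the last `k` open-pupil samples before index i (diameter above
# half the global baseline and valid); falls back to the global baseline.
local_baseline <- function(d, v, i, global_b, k = 15L) {
  pre <- which(v[seq_len(i - 1L)] & d[seq_len(i - 1L)] > 0.5 * global_b)
  if (!length(pre)) return(global_b)
  median(d[tail(pre, k)])
}

# Interpolated time at which the diameter crosses `level` on a closing
# (falling) or re-opening (rising) ramp, searching the samples `idx` in
# order. Returns NA when the level is not bracketed.
level_crossing <- function(t, d, idx, level, rising) {
  dd <- d[idx]
  if (length(idx) < 2) return(NA_real_)
  if (rising) {
    k <- which(dd[-length(dd)] < level & dd[-1] >= level)
    k <- if (length(k)) k[length(k)] else return(NA_real_)
  } else {
    k <- which(dd[-length(dd)] >= level & dd[-1] < level)
    k <- if (length(k)) k[1] else return(NA_real_)
  }
  i1 <- idx[k]; i2 <- idx[k + 1]
  if (d[i2] == d[i1]) return(NA_real_)
  t[i1] + (level - d[i1]) * (t[i2] - t[i1]) / (d[i2] - d[i1])
}

# Sub-sample edge timing: interpolate the 25%- and 75%-of-baseline
# crossings on a ramp and extend their line to the full-baseline crossing
# (the moment the lid leaves/regains the open-pupil diameter). Assumes
# only that the occlusion edge is approximately linear.
edge_time <- function(t, d, idx, b, rising) {
  t25 <- level_crossing(t, d, idx, 0.25 * b, rising)
  t75 <- level_crossing(t, d, idx, 0.75 * b, rising)
  if (is.na(t25) || is.na(t75) || t25 == t75) return(NA_real_)
  1.5 * t75 - 0.5 * t25
}

#' Detect blinks in a pupil trace
#'
#' A candidate opens at any sample where the fractional diameter drop from
#' the previous sample is at least `diameter_drop_rate` of the local
#' baseline, or where the validity flag flips off together with a vertical
#' pupil-center displacement of at least `center_y_disp` baseline SDs. The
#' candidate closes when the diameter recovers to at least 50% of the local
#' pre-event baseline with tracking valid. Candidates separated by less
#' than `merge_gap_s` are merged; events outside
#' `[min_dur_s, max_dur_s]` are discarded. Onset and offset are refined to
#' sub-sample precision by extrapolating the closing/opening ramps to the
#' baseline crossing.
#'
#' Invalid runs that lack the rapid-occlusion signature are labelled track
#' loss, not blinks; they are reported in the `track_loss` attribute of the
#' result. An all-invalid trace yields zero events and quality flag
#' `"track_loss"`.
#'
#' @param trace a [pupil_trace()] at 30 Hz (see [downsample_trace()]).
#' @param params a [detector_params()].
#' @return tibble `onset_s, duration_s` (sorted, non-overlapping) with
#'   attributes `quality` (`"ok"`/`"track_loss"`), `track_loss` (tibble of
#'   excluded invalid runs) and `n_candidates_raw` (opening transitions
#'   before merging/filtering).
#' @export
detect_blinks <- function(trace, params = detector_params()) {
  rate <- attr(trace, "sample_rate_hz")
  if (is.null(rate) || abs(rate - 30) > 1e-6) {
    abort("detect_blinks: trace must be at 30 Hz (use downsample_trace())",
          class = "blinkengage_validation_error")
  }
  empty <- tibble(onset_s = numeric(0), duration_s = numeric(0))
  d <- trace$diameter; v <- trace$valid; cy <- trace$center_y; tt <- trace$t
  n <- length(d)
  if (!any(v)) {
    attr(empty, "quality") <- "track_loss"
    attr(empty, "track_loss") <- tibble(start_s = tt[1], end_s = tt[n])
    attr(empty, "n_candidates_raw") <- 0L
    return(empty)
  }
  open_d <- d[v & d > 0]
  global_b <- if (length(open_d)) median(open_d) else NA_real_
  if (!isTRUE(global_b > 0)) {
    attr(empty, "quality") <- "track_loss"
    attr(empty, "track_loss") <- tibble(start_s = tt[1], end_s = tt[n])
    attr(empty, "n_candidates_raw") <- 0L
    return(empty)
  }
  cy_sd <- mad(cy[v])

  # opening triggers
  drop_frac <- c(0, -diff(d)) / global_b
  trig_drop <- drop_frac >= params$diameter_drop_rate
  dropout <- c(FALSE, v[-n] & !v[-1])
  dcy <- abs(c(0, diff(cy)))
  trig_dropout <- dropout &
    (if (cy_sd > 0) dcy >= params$center_y_disp * cy_sd else dcy > 0)
  trig <- which(trig_drop | trig_dropout)
  n_raw <- length(trig)

  cands <- list()
  consumed_until <- 0L
  for (i in trig) {
    if (i <= consumed_until) next
    b_loc <- local_baseline(d, v, i, global_b)
    if (trig_drop[i]) {
      # first sample of the opening transition; walk back over any earlier
      # part of the closing ramp
      onset_idx <- i - 1L
      while (onset_idx > 1L && d[onset_idx] < 0.9 * b_loc &&
             (i - onset_idx) <= 5L) onset_idx <- onset_idx - 1L
    } else {
      onset_idx <- i             # pure tracking dropout: transition is here
      while (onset_idx > 1L && d[onset_idx - 1L] < 0.9 * b_loc &&
             (i - onset_idx) <= 5L) onset_idx <- onset_idx - 1L
    }
    j <- i
    while (j <= n && !(v[j] && d[j] >= 0.5 * b_loc)) j <- j + 1L
    close_idx <- min(j, n)
    cands[[length(cands) + 1L]] <- list(onset = onset_idx,
                                        close = close_idx, b = b_loc)
    consumed_until <- close_idx
  }

  # merge candidates separated by less than merge_gap_s
  if (length(cands) > 1) {
    merged <- list(cands[[1]])
    for (k in 2:length(cands)) {
      prev <- merged[[length(merged)]]
      gap <- tt[cands[[k]]$onset] - tt[prev$close]
      if (gap < params$merge_gap_s) {
        prev$close <- cands[[k]]$close
        merged[[length(merged)]] <- prev
      } else {
        merged[[length(merged) + 1L]] <- cands[[k]]
      }
    }
    cands <- merged
  }

  onsets <- numeric(0); durs <- numeric(0)
  covered <- rep(FALSE, n)
  dt <- 1 / rate
  for (cand in cands) {
    io <- cand$onset; ic <- cand$close; b <- cand$b
    span <- io:ic
    min_idx <- span[which.min(d[span])]
    t_on <- edge_time(tt, d, io:min_idx, b, rising = FALSE)
    if (is.na(t_on)) t_on <- tt[io]
    rise_idx <- min_idx:min(n, ic + 3L)
    t_off <- edge_time(tt, d, rise_idx, b, rising = TRUE)
    if (is.na(t_off)) t_off <- tt[ic]
    t_on <- max(t_on, tt[io] - dt)
    t_off <- min(max(t_off, t_on + dt), tt[min(n, ic + 3L)] + dt)
    dur <- t_off - t_on
    # occlusion span: time the pupil was lost or below half baseline;
    # separates real blinks from single-sample glitches
    occ_span <- dt * sum(!v[span] | d[span] < 0.5 * b)
    if (occ_span >= params$min_dur_s &&
        dur >= params$min_dur_s && dur <= params$max_dur_s) {
      onsets <- c(onsets, t_on); durs <- c(durs, dur)
      covered[span] <- TRUE
    }
  }

  # clip any residual overlap from sub-sample refinement
  if (length(onsets) > 1) {
    ord <- order(onsets)
    onsets <- onsets[ord]; durs <- durs[ord]
    for (k in 2:length(onsets)) {
      prev_end <- onsets[k - 1] + durs[k - 1]
      if (onsets[k] < prev_end) {
        durs[k] <- durs[k] - (prev_end - onsets[k])
        onsets[k] <- prev_end
      }
    }
    keep <- durs >= params$min_dur_s
    onsets <- onsets[keep]; durs <- durs[keep]
  }

  # invalid runs not explained by a blink candidate -> track loss
  loss <- list()
  r <- rle(!v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (!any(covered[starts[k]:ends[k]])) {
      loss[[length(loss) + 1L]] <- tibble(start_s = tt[starts[k]],
                                          end_s = tt[ends[k]])
    }
  }
  out <- tibble(onset_s = onsets, duration_s = durs)
  attr(out, "quality") <- "ok"
  attr(out, "track_loss") <- if (length(loss)) dplyr::bind_rows(loss) else
    tibble(start_s = numeric(0), end_s = numeric(0))
  attr(out, "n_candidates_raw") <- n_raw
  out
}

#' Score detected blinks against ground truth
#'
#' Greedy one-to-one onset matching within `match_tol_s`: truth events are
#' visited in time order and matched to the nearest unmatched detection.
#'
#' @param truth,detected tibbles `onset_s, duration_s`, sorted by onset.
#' @param match_tol_s matching tolerance in seconds (> 0).
#' @param exposure_s exposure used for the false-alarm rate; defaults to
#'   the span covered by the union of both event lists.
#' @return list: `n_truth`, `n_detected`, `n_matched`, `sensitivity_pct`,
#'   `false_alarms_per_min`, `mean_abs_duration_error_s`,
#'   `mean_abs_onset_error_s`.
#' @export
detection_report <- function(truth, detected, match_tol_s = 0.1,
                             exposure_s = NULL) {
  stopifnot(match_tol_s > 0)
  if (is.null(exposure_s)) {
    ends <- c(truth$onset_s + truth$duration_s,
              detected$onset_s + detected$duration_s, 0)
    exposure_s <- max(ends)
  }
  used <- rep(FALSE, nrow(detected))
  dur_err <- numeric(0); on_err <- numeric(0)
  n_match <- 0L
  for (k in seq_len(nrow(truth))) {
    diffs <- abs(detected$onset_s - truth$onset_s[k])
    diffs[used] <- Inf
    j <- which.min(diffs)
    if (length(j) && is.finite(diffs[j]) && diffs[j] <= match_tol_s) {
      used[j] <- TRUE
      n_match <- n_match + 1L
      on_err <- c(on_err, diffs[j])
      dur_err <- c(dur_err,
                   abs(detected$duration_s[j] - truth$duration_s[k]))
    }
  }
  list(
    n_truth = nrow(truth),
    n_detected = nrow(detected),
    n_matched = n_match,
    sensitivity_pct = if (nrow(truth)) 100 * n_match / nrow(truth) else NA_real_,
    false_alarms_per_min = if (exposure_s > 0)
      60 * (nrow(detected) - n_match) / exposure_s else NA_real_,
    mean_abs_duration_error_s = if (n_match) mean(dur_err) else NA_real_,
    mean_abs_onset_error_s = if (n_match) mean(on_err) else NA_real_
  )
}
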
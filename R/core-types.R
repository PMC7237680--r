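# Domain containers are plain tibbles with fixed column contracts:
#
#   schedules:    video_id, condition_s, scene_index, category, onset_s, offset_s
#   events:       participant_id, video_id, onset_s, duration_s
#   participants: participant_id, group, parity
#
# Validators below enforce the study invariants; readers always validate,
# constructors used in tests may build unvalidated toy tables directly.

SCHEDULE_COLS <- c("video_id", "condition_s", "scene_index", "category",
                   "onset_s", "offset_s")
EVENT_COLS <- c("participant_id", "video_id", "onset_s", "duration_s")
PARTICIPANT_COLS <- c("participant_id", "group", "parity")

#' Validate a scene-schedule table
#'
#' Checks, per composite video: scenes are 1-indexed, strictly contiguous
#' (each scene's offset equals the next scene's onset), all scene durations
#' equal the video's alternation condition, categories strictly alternate
#' between land and water, and the total duration lies within the
#' 90--160.2 s composite-video envelope.
#'
#' @param schedules tibble with columns
#'   `video_id, condition_s, scene_index, category, onset_s, offset_s`.
#' @param tol numeric tolerance (seconds) for contiguity/duration checks.
#' @return the input, invisibly, if valid; otherwise an error naming the
#'   offending video.
#' @export
validate_schedules <- function(schedules, tol = 1e-9) {
  check_cols(schedules, SCHEDULE_COLS, "schedules")
  if (!all(schedules$category %in% SCENE_CATEGORIES)) {
    abort("schedules: category must be 'land' or 'water'",
          class = "blinkengage_validation_error")
  }
  if (!all(schedules$condition_s %in% SCENE_CONDITIONS)) {
    abort(paste0("schedules: condition_s must be one of ",
                 paste(SCENE_CONDITIONS, collapse = ", ")),
          class = "blinkengage_validation_error")
  }
  for (vid in unique(schedules$video_id)) {
    sc <- schedules[schedules$video_id == vid, ]
    sc <- sc[order(sc$scene_index), ]
    fail <- function(msg) {
      abort(sprintf("schedule for video '%s': %s", vid, msg),
            class = "blinkengage_validation_error")
    }
    if (!identical(as.integer(sc$scene_index), seq_len(nrow(sc)))) {
      fail("scene_index must be 1..n_scenes")
    }
    if (length(unique(sc$condition_s)) != 1L) fail("condition_s must be constant")
    if (abs(sc$onset_s[1]) > tol) fail("first scene must start at 0 s")
    if (nrow(sc) > 1 &&
        any(abs(sc$offset_s[-nrow(sc)] - sc$onset_s[-1]) > tol)) {
      fail("scenes must be contiguous (offset[i] == onset[i+1])")
    }
    if (any(abs((sc$offset_s - sc$onset_s) - sc$condition_s[1]) > tol)) {
      fail("every scene duration must equal condition_s")
    }
    if (nrow(sc) > 1 && any(sc$category[-1] == sc$category[-nrow(sc)])) {
      fail("categories must strictly alternate")
    }
    dur <- sc$offset_s[nrow(sc)]
    if (dur < VIDEO_DURATION_RANGE[1] - tol ||
        dur > VIDEO_DURATION_RANGE[2] + tol) {
      fail(sprintf("total duration %.3f s outside [%g, %g]",
                   dur, VIDEO_DURATION_RANGE[1], VIDEO_DURATION_RANGE[2]))
    }
  }
  invisible(schedules)
}

#' Validate a blink-event table
#'
#' Within each participant-video series, events must be sorted by onset,
#' have strictly positive durations, and must not overlap (a blink cannot
#' begin before the previous one has ended).
#'
#' @param events tibble with columns
#'   `participant_id, video_id, onset_s, duration_s`.
#' @return the input, invisibly, if valid.
#' @export
validate_events <- function(events) {
  check_cols(events, EVENT_COLS, "events")
  if (nrow(events) == 0) return(invisible(events))
  if (any(events$duration_s <= 0)) {
    abort("events: duration_s must be > 0",
          class = "blinkengage_validation_error")
  }
  if (any(events$onset_s < 0)) {
    abort("events: onset_s must be >= 0",
          class = "blinkengage_validation_error")
  }
  split_keys <- paste(events$participant_id, events$video_id, sep = "\r")
  for (key in unique(split_keys)) {
    ev <- events[split_keys == key, ]
    ev <- ev[order(ev$onset_s), ]
    if (nrow(ev) > 1) {
      ends <- ev$onset_s[-nrow(ev)] + ev$duration_s[-nrow(ev)]
      if (any(ends > ev$onset_s[-1] + 1e-12)) {
        abort(sprintf(
          "overlapping blinks for participant '%s', video '%s'",
          ev$participant_id[1], ev$video_id[1]),
          class = "blinkengage_validation_error")
      }
    }
  }
  invisible(events)
}

#' Validate a participant-metadata table
#'
#' @param participants tibble with columns `participant_id, group, parity`.
#' @return the input, invisibly, if valid.
#' @export
validate_participants <- function(participants) {
  check_cols(participants, PARTICIPANT_COLS, "participants")
  if (anyDuplicated(participants$participant_id)) {
    abort("participants: duplicated participant_id",
          class = "blinkengage_validation_error")
  }
  if (!all(participants$group %in% TASK_GROUPS)) {
    abort("participants: unknown group label (expected land_counter/water_counter)",
          class = "blinkengage_parse_error")
  }
  if (!all(participants$parity %in% PARITY_LABELS)) {
    abort("participants: unknown parity label (expected attended_odd/attended_even)",
          class = "blinkengage_parse_error")
  }
  invisible(participants)
}

#' Cross-validate participant records against schedules
#'
#' Checks that every video referenced by a participant's events has a
#' schedule, that each participant's videos share one first-scene category,
#' and that the recorded parity is consistent with group x first-scene
#' category (a land counter whose videos open on land attended the odd
#' scenes).
#'
#' @param participants,events,schedules domain tables (see
#'   [validate_participants()], [validate_events()], [validate_schedules()]).
#' @return invisibly, a tibble of per-participant first-scene categories.
#' @export
validate_records <- function(participants, events, schedules) {
  validate_participants(participants)
  validate_events(events)
  unknown <- setdiff(events$video_id, schedules$video_id)
  if (length(unknown)) {
    abort(sprintf("events reference video(s) with no schedule: %s",
                  paste(unknown, collapse = ", ")),
          class = "blinkengage_validation_error")
  }
  firsts <- schedules[schedules$scene_index == 1,
                      c("video_id", "category")]
  out <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    vids <- unique(events$video_id[events$participant_id == pid])
    fc <- unique(firsts$category[firsts$video_id %in% vids])
    if (length(fc) > 1) {
      abort(sprintf(
        "participant '%s': videos mix first-scene categories (%s)",
        pid, paste(fc, collapse = ", ")),
        class = "blinkengage_validation_error")
    }
    if (length(fc) == 1) {
      expected <- parity_label(participants$group[i], fc)
      if (expected != participants$parity[i]) {
        abort(sprintf(
          "participant '%s': parity '%s' inconsistent with group '%s' and first scene '%s'",
          pid, participants$parity[i], participants$group[i], fc),
          class = "blinkengage_validation_error")
      }
    }
    out[[i]] <- tibble(participant_id = pid,
                       first_category = if (length(fc)) fc else NA_character_)
  }
  invisible(dplyr::bind_rows(out))
}

#' Construct a pupil trace
#'
#' A pupil trace holds uniformly sampled pupil diameter (arbitrary device
#' units), vertical pupil-center position (pixels, increasing downward), and
#' a per-sample validity flag (whether the tracker found the pupil).
#'
#' @param t sample times in seconds, strictly increasing, uniformly spaced
#'   at `1/sample_rate_hz`.
#' @param diameter,center_y numeric channels, same length as `t`.
#' @param valid logical channel, same length as `t`.
#' @param sample_rate_hz sampling rate in Hz.
#' @return a tibble of class `pupil_trace` with attribute `sample_rate_hz`.
#' @export
pupil_trace <- function(t, diameter, center_y, valid, sample_rate_hz) {
  n <- length(t)
  if (length(diameter) != n || length(center_y) != n || length(valid) != n) {
    abort("pupil_trace: channels must have equal length",
          class = "blinkengage_validation_error")
  }
  if (n >= 2) {
    dt <- diff(t)
    if (any(dt <= 0) || any(abs(dt - 1 / sample_rate_hz) > 1e-6)) {
      abort("pupil_trace: t must be strictly increasing with spacing 1/sample_rate_hz",
            class = "blinkengage_validation_error")
    }
  }
  out <- tibble(t = as.numeric(t), diameter = as.numeric(diameter),
                center_y = as.numeric(center_y), valid = as.logical(valid))
  attr(out, "sample_rate_hz") <- sample_rate_hz
  class(out) <- c("pupil_trace", class(out))
  out
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("<pupil_trace: %d samples @ %g Hz, %.1f%% valid>\n",
              nrow(x), attr(x, "sample_rate_hz"), 100 * mean(x$valid)))
  NextMethod()
}

check_cols <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort(sprintf("%s must be a data frame", what),
          class = "blinkengage_validation_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "blinkengage_parse_error")
  }
  invisible(df)
}

# Half-open window membership: onset in [start, end).
in_window <- function(onset, start, end) onset >= start & onset < end
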
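# Readers/writers for the pipeline's CSV interchange formats. Comma
# separated, UTF-8, '.' decimal, mandatory header; doubles written at full
# precision so write-then-read is the identity to <= 1e-9 relative error.

read_typed_csv <- function(path, col_types, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s: file not found: %s", what, path),
          class = "blinkengage_parse_error")
  }
  out <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    abort(sprintf("%s: malformed row at line %d of %s (%s)",
                  what, prob$row[1] + 1L, path, prob$expected[1]),
          class = "blinkengage_parse_error")
  }
  out
}

no_na <- function(df, what, path) {
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    abort(sprintf("%s: malformed row at line %d of %s (missing value)",
                  what, bad[1] + 1L, path),
          class = "blinkengage_parse_error")
  }
  df
}

#' Read scene schedules
#'
#' Reads the land/water alternation timeline of each composite video from
#' CSV (`video_id,condition_s,scene_index,category,onset_s,offset_s`, one
#' row per scene) and validates all schedule invariants.
#'
#' @param path CSV file path.
#' @return validated schedules tibble.
#' @seealso [validate_schedules()], [write_schedules()]
#' @export
read_schedules <- function(path) {
  sch <- read_typed_csv(path, readr::cols(
    video_id = readr::col_character(),
    condition_s = readr::col_double(),
    scene_index = readr::col_integer(),
    category = readr::col_character(),
    onset_s = readr::col_double(),
    offset_s = readr::col_double()
  ), "schedules")
  check_cols(sch, SCHEDULE_COLS, "schedules")
  no_na(sch, "schedules", path)
  sch <- dplyr::arrange(sch, .data$video_id, .data$scene_index)
  validate_schedules(sch)
  sch
}

#' @rdname read_schedules
#' @param schedules schedules tibble to write.
#' @export
write_schedules <- function(schedules, path) {
  validate_schedules(schedules)
  readr::write_csv(schedules, path)
  invisible(path)
}

#' Read blink events (and embedded participant metadata)
#'
#' Reads one row per blink from CSV
#' (`participant_id,group,parity,video_id,onset_s,duration_s`), groups and
#' sorts events per participant-video, and validates them. Participants
#' listed in `participants` but absent from the event file are kept with
#' empty event lists (sparse blinkers are legitimate data).
#'
#' @param path events CSV path.
#' @param participants optional participant metadata tibble
#'   (`participant_id,group,parity`); rows found in the event file are
#'   checked against it.
#' @return list with elements `participants` (tibble) and `events` (tibble,
#'   sorted by participant, video, onset).
#' @export
read_events <- function(path, participants = NULL) {
  ev <- read_typed_csv(path, readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    parity = readr::col_character(),
    video_id = readr::col_character(),
    onset_s = readr::col_double(),
    duration_s = readr::col_double()
  ), "events")
  check_cols(ev, c("participant_id", "group", "parity", EVENT_COLS[-1]),
             "events")
  no_na(ev, "events", path)
  meta <- dplyr::distinct(ev, .data$participant_id, .data$group, .data$parity)
  if (anyDuplicated(meta$participant_id)) {
    abort("events: participant listed with conflicting group/parity",
          class = "blinkengage_validation_error")
  }
  validate_participants(meta)
  if (!is.null(participants)) {
    validate_participants(participants)
    merged <- dplyr::left_join(meta, participants, by = "participant_id",
                               suffix = c("", ".meta"))
    if (any(is.na(merged$group.meta)) ||
        any(merged$group != merged$group.meta) ||
        any(merged$parity != merged$parity.meta)) {
      abort("events: metadata disagrees with participants table",
            class = "blinkengage_validation_error")
    }
    meta <- participants
  }
  events <- dplyr::arrange(
    ev[, EVENT_COLS], .data$participant_id, .data$video_id, .data$onset_s)
  validate_events(events)
  list(participants = as_tibble(meta), events = as_tibble(events))
}

#' Write blink events with participant metadata
#'
#' Inverse of [read_events()]: one CSV row per blink carrying the
#' participant's group and parity. Participants with no events contribute no
#' rows; persist them via [write_participants()].
#'
#' @param participants,events domain tables.
#' @param path output CSV path.
#' @export
write_events <- function(participants, events, path) {
  validate_participants(participants)
  validate_events(events)
  out <- dplyr::inner_join(participants, events, by = "participant_id")
  out <- dplyr::arrange(out, .data$participant_id, .data$video_id,
                        .data$onset_s)
  readr::write_csv(
    out[, c("participant_id", "group", "parity", "video_id",
            "onset_s", "duration_s")], path)
  invisible(path)
}

#' Read or write participant metadata
#'
#' @param path CSV path (`participant_id,group,parity`).
#' @return `read_participants()`: validated tibble.
#' @export
read_participants <- function(path) {
  pp <- read_typed_csv(path, readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    parity = readr::col_character()
  ), "participants")
  check_cols(pp, PARTICIPANT_COLS, "participants")
  no_na(pp, "participants", path)
  validate_participants(pp)
  pp
}

#' @rdname read_participants
#' @param participants tibble to write.
#' @export
write_participants <- function(participants, path) {
  validate_participants(participants)
  readr::write_csv(participants[, PARTICIPANT_COLS], path)
  invisible(path)
}

#' Read or write a pupil trace
#'
#' Trace CSVs hold `t,diameter,center_y,valid` with the sampling rate
#' recoverable from the time stamps.
#'
#' @param path CSV path.
#' @return `read_pupil_trace()`: a [pupil_trace()].
#' @export
read_pupil_trace <- function(path) {
  tr <- read_typed_csv(path, readr::cols(
    t = readr::col_double(),
    diameter = readr::col_double(),
    center_y = readr::col_double(),
    valid = readr::col_logical()
  ), "pupil trace")
  no_na(tr, "pupil trace", path)
  if (nrow(tr) < 2) {
    abort("pupil trace: need at least 2 samples",
          class = "blinkengage_validation_error")
  }
  rate <- 1 / median(diff(tr$t))
  pupil_trace(tr$t, tr$diameter, tr$center_y, tr$valid,
              sample_rate_hz = round(rate, 6))
}

#' @rdname read_pupil_trace
#' @param trace a [pupil_trace()] to write.
#' @export
write_pupil_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[, c("t", "diameter", "center_y", "valid")],
                   path)
  invisible(path)
}
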
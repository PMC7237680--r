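# End-to-end orchestration: simulate (or ingest) -> rates -> both
# classifiers -> classification strength -> group statistics, with one
# config, deterministic per-stage seeds derived from a single global seed,
# and a JSON run manifest echoing the configuration.

#' Pipeline run configuration
#'
#' @param cohort a [cohort_params()] (its `seed` field is overridden by the
#'   derived stage seed).
#' @param detector a [detector_params()] (used only when traces are
#'   rendered/detected).
#' @param svm an [svm_config()].
#' @param intervals_s content-unaware interval sizes in seconds.
#' @param conditions_s alternation conditions in seconds.
#' @param target_duration_s target composite-video duration in seconds.
#' @param n_perm permutations for the content-unaware null (applied at the
#'   interval sizes in `perm_intervals_s`; 0 disables).
#' @param perm_intervals_s interval sizes at which the permutation test is
#'   run (the dominant cost; default 5 s only).
#' @param output_dir directory for the output CSVs and manifest.
#' @param global_seed integer master seed; per-stage seeds are derived from
#'   it and the stage name, so reconfiguring one stage never perturbs
#'   another stage's randomness.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_params(),
                       detector = detector_params(),
                       svm = svm_config(),
                       intervals_s = 1:10,
                       conditions_s = SCENE_CONDITIONS,
                       target_duration_s = 160,
                       n_perm = 199,
                       perm_intervals_s = 5,
                       output_dir = tempfile("blinkengage_run_"),
                       global_seed = 1L) {
  cfg <- list(cohort = cohort, detector = detector, svm = svm,
              intervals_s = intervals_s, conditions_s = conditions_s,
              target_duration_s = target_duration_s,
              n_perm = n_perm, perm_intervals_s = perm_intervals_s,
              output_dir = output_dir,
              global_seed = as.integer(global_seed))
  class(cfg) <- "run_config"
  cfg
}

#' Derive a stage seed from the global seed and stage name
#'
#' Deterministic 31-bit hash mixing the global seed with the stage name.
#'
#' @param global_seed integer master seed.
#' @param stage stage name string.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- as.double(global_seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates the cohort, computes pooled and per-condition scene rates,
#' interval feature vectors, the content-aware ROC, the content-unaware
#' LOOCV SVM sweep (with optional permutation tests), per-condition
#' likelihood ratios with the regression suite, and the inferential
#' statistics. Writes all outputs as CSV plus a JSON manifest, and returns
#' the manifest invisibly.
#'
#' @param config a [run_config()].
#' @return (invisibly) the manifest list, with headline metrics under
#'   `$headline`.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$output_dir, f)
  stage <- "simulate"
  tryCatch({
    config$cohort$seed <- stage_seed(config$global_seed, "simulate")
    cohort <- simulate_cohort(config$cohort,
                              target_duration_s = config$target_duration_s,
                              conditions = config$conditions_s)
    write_schedules(cohort$schedules, out_path("schedules.csv"))
    write_participants(cohort$participants, out_path("participants.csv"))
    write_events(cohort$participants, cohort$events, out_path("events.csv"))

    stage <- "rates"
    rates <- scene_rates(cohort$participants, cohort$events,
                         cohort$schedules)
    rates_cond <- scene_rates(cohort$participants, cohort$events,
                              cohort$schedules, by_condition = TRUE)
    readr::write_csv(rates, out_path("scene_rates.csv"))
    readr::write_csv(rates_cond, out_path("scene_rates_by_condition.csv"))
    profiles_long <- dplyr::bind_rows(lapply(
      seq_len(nrow(cohort$participants)), function(i) {
        pid <- cohort$participants$participant_id[i]
        vids <- participant_videos(cohort$participants$group[i],
                                   cohort$participants$parity[i],
                                   cohort$schedules)
        dplyr::bind_rows(lapply(config$intervals_s, function(iv) {
          out <- interval_vector(
            cohort$events[cohort$events$participant_id == pid, ],
            cohort$schedules, iv, vids)
          out$participant_id <- pid
          out$interval_s <- iv
          out
        }))
      }))
    readr::write_csv(profiles_long, out_path("rate_profiles.csv"))

    stage <- "classify_aware"
    roc <- classify_content_aware(rates$metric, rates$group)
    readr::write_csv(
      tibble(threshold = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr),
      out_path("roc.csv"))

    stage <- "classify_unaware"
    perm_on <- length(config$perm_intervals_s) > 0 && config$n_perm > 0
    plain_intervals <- if (perm_on)
      setdiff(config$intervals_s, config$perm_intervals_s) else
        config$intervals_s
    sweep <- classify_unaware_sweep(
      cohort$participants, cohort$events, cohort$schedules,
      intervals_s = plain_intervals,
      config = config$svm, n_perm = 0,
      seed = stage_seed(config$global_seed, "classify_unaware"))
    if (perm_on) {
      sweep_perm <- classify_unaware_sweep(
        cohort$participants, cohort$events, cohort$schedules,
        intervals_s = intersect(config$intervals_s,
                                config$perm_intervals_s),
        config = config$svm, n_perm = config$n_perm,
        seed = stage_seed(config$global_seed, "classify_unaware"))
      for (nm in names(attr(sweep_perm, "reports"))) {
        pt <- attr(sweep_perm, "reports")[[nm]]
        readr::write_csv(
          tibble(percent_correct = pt$null_percent_correct),
          out_path(sprintf("null_distribution_%s.csv", nm)))
      }
      sweep <- dplyr::arrange(dplyr::bind_rows(sweep, sweep_perm),
                              .data$interval_s)
    }
    readr::write_csv(sweep, out_path("classification_unaware.csv"))

    stage <- "strength"
    strength <- classification_strength(rates_cond)
    readr::write_csv(strength, out_path("likelihood.csv"))
    regs <- dplyr::bind_rows(lapply(
      sort(unique(strength$condition_s)), function(cond) {
        sc <- strength[strength$condition_s == cond, ]
        out <- strength_regressions(sc$bpm_condition, sc$log_lr,
                                    n_comparisons =
                                      length(unique(strength$condition_s)))
        out$condition_s <- cond
        out[, c("condition_s", setdiff(names(out), "condition_s"))]
      }))
    readr::write_csv(regs[, setdiff(names(regs), "coefficients")],
                     out_path("regressions.csv"))

    stage <- "stats"
    stats_tbl <- dplyr::bind_rows(
      group_t_test(rates$bpm_session, rates$group),
      dplyr::mutate(
        interaction_anova(rates$bpm_land, rates$bpm_water, rates$group),
        df = .data$df2, df1 = NULL, df2 = NULL)
    )
    readr::write_csv(stats_tbl, out_path("stats.csv"))
    timescale <- timescale_paired_tests(rates_cond)
    readr::write_csv(timescale, out_path("timescale_tests.csv"))

    manifest <- list(
      package = "blinkengage",
      version = as.character(utils::packageVersion("blinkengage")),
      global_seed = config$global_seed,
      stage_seeds = list(
        simulate = stage_seed(config$global_seed, "simulate"),
        classify_unaware = stage_seed(config$global_seed,
                                      "classify_unaware")
      ),
      config = list(
        cohort = unclass(config$cohort),
        svm = unclass(config$svm),
        intervals_s = config$intervals_s,
        conditions_s = config$conditions_s,
        target_duration_s = config$target_duration_s,
        n_perm = config$n_perm,
        perm_intervals_s = config$perm_intervals_s
      ),
      headline = list(
        auc = roc$auc,
        sensitivity_pct = roc$sensitivity_pct,
        specificity_pct = roc$specificity_pct,
        percent_correct_by_interval =
          setNames(as.list(sweep$percent_correct),
                   sprintf("interval_%g", sweep$interval_s)),
        permutation_p =
          setNames(as.list(sweep$p_value[!is.na(sweep$p_value)]),
                   sprintf("interval_%g",
                           sweep$interval_s[!is.na(sweep$p_value)])),
        interaction_p = stats_tbl$p_value[stats_tbl$test ==
                                            "scene_by_group_interaction"],
        all_timescales_significant = all(timescale$p_corrected < 0.05,
                                         na.rm = TRUE)
      )
    )
    jsonlite::write_json(manifest, out_path("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "blinkengage_runtime_error", parent = e)
  })
}
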
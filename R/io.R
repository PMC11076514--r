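# ---- events -----------------------------------------------------------------

#' Read and validate a keypress events table
#'
#' Expects a CSV with header `subject_id,session,block,block_type,t,key`;
#' `t` in seconds from block onset, `key` one of `left`/`right`. Malformed
#' rows (bad key, out-of-range or non-monotone times within a block) raise a
#' validation error naming the offending rows.
#'
#' @param path CSV file path.
#' @param block_duration Maximum legal event time (default 120 s).
#' @return A validated tibble sorted by subject, session, block, time.
#' @export
read_events <- function(path, block_duration = 120) {
  ev <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject_id", "session", "block", "block_type", "t", "key")
  miss <- setdiff(required, names(ev))
  if (length(miss)) {
    abort(sprintf("events file is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  bad_key <- which(!ev$key %in% .directions)
  if (length(bad_key)) {
    abort(sprintf("invalid `key` value(s) at data row(s) %s",
                  paste(head(bad_key, 10), collapse = ", ")))
  }
  bad_t <- which(!is.finite(ev$t) | ev$t < 0 | ev$t > block_duration)
  if (length(bad_t)) {
    abort(sprintf("event time out of [0, %g] at data row(s) %s",
                  block_duration, paste(head(bad_t, 10), collapse = ", ")))
  }
  ev <- dplyr::arrange(ev, .data$subject_id, .data$session, .data$block,
                       .data$t)
  ev
}

#' Write a keypress events table
#' @param events Events tibble.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

# ---- schedules --------------------------------------------------------------

#' Read/write a physical switch schedule as JSON
#'
#' Schedules are stored as `{block_duration, switch_times, directions}`.
#'
#' @param schedule A `switch_schedule`.
#' @param path JSON file path.
#' @return `write_schedule()`: `path` invisibly; `read_schedule()`: a
#'   `switch_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "switch_schedule"))
  jsonlite::write_json(unclass(schedule), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sched <- structure(
    list(block_duration = x$block_duration,
         switch_times = as.numeric(x$switch_times),
         directions = as.character(x$directions)),
    class = "switch_schedule"
  )
  if (is.unsorted(sched$switch_times, strictly = TRUE) ||
      any(sched$switch_times <= 0) ||
      any(sched$switch_times >= sched$block_duration)) {
    abort("schedule switch_times must be strictly increasing within the block.")
  }
  if (length(sched$directions) != length(sched$switch_times) + 1) {
    abort("schedule needs one more direction than switch times.")
  }
  sched
}

# ---- cohort persistence -----------------------------------------------------

#' Write a simulated cohort to a directory
#'
#' Writes `sessions.csv`, `events.csv` (when present), `counts.csv` and
#' `schedule.json`.
#'
#' @param cohort An `sfm_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sfm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$sessions, file.path(dir, "sessions.csv"))
  readr::write_csv(cohort$bistable_counts, file.path(dir, "counts.csv"))
  if (!is.null(cohort$events)) {
    write_events(cohort$events, file.path(dir, "events.csv"))
  }
  write_schedule(cohort$schedule, file.path(dir, "schedule.json"))
  invisible(dir)
}

# ---- pipeline ---------------------------------------------------------------

#' Run the simulation-scoring-statistics pipeline end to end
#'
#' Simulates (or reads) a cohort, scores it, runs the statistical battery,
#' and writes all artifacts plus a run manifest to `out_dir`. The run is
#' fully determined by the configuration's master seed.
#'
#' @param config A named list (or path to a YAML file) with optional entries:
#'   `seed` (master seed, default 1), `n_per_group`, `cohort` (further
#'   [cohort_spec()] overrides), `cylinder` ([cylinder_params()] overrides),
#'   `window` (4), `min_correct` (7), `events_file` (skip simulation, score
#'   an existing events CSV with `schedule_file`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `cohort`, `scores`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("cylsfm_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  params <- do.call(cylinder_params, config$cylinder %||% list())
  window <- config$window %||% 4
  min_correct <- config$min_correct %||% 7

  if (!is.null(config$events_file)) {
    events <- read_events(config$events_file, params$block_duration)
    schedule <- if (!is.null(config$schedule_file)) {
      read_schedule(config$schedule_file)
    } else {
      real_switch_schedule(params, "paper")
    }
    cohort <- NULL
    scores <- score_cohort(events, schedule, window, min_correct,
                           params$block_duration)
    sessions <- NULL
  } else {
    spec_args <- config$cohort %||% list()
    spec_args$seed <- seed
    if (!is.null(config$n_per_group)) {
      spec_args$n_per_group <- unlist(config$n_per_group)
    }
    spec <- do.call(cohort_spec, spec_args)
    cohort <- simulate_cohort(spec, params)
    write_cohort(cohort, out_dir)
    scores <- score_cohort(cohort, window = window, min_correct = min_correct)
    sessions <- cohort$sessions
  }

  readr::write_csv(scores$subjects, file.path(out_dir, "metrics.csv"))
  readr::write_csv(scores$blocks, file.path(out_dir, "block_metrics.csv"))
  readr::write_csv(scores$durations, file.path(out_dir, "durations.csv"))

  report <- NULL
  if (!is.null(sessions)) {
    report <- run_stats(scores, sessions)
    jsonlite::write_json(tidy(report), file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  incl <- scores$subjects
  if (!is.null(sessions)) {
    incl <- dplyr::left_join(
      incl, dplyr::distinct(sessions, .data$subject_id, .data$group),
      by = "subject_id"
    )
  } else {
    incl$group <- "unknown"
  }
  counts <- incl |>
    dplyr::filter(.data$session == 1) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(generated = dplyr::n(),
                     included = sum(.data$included),
                     excluded = sum(!.data$included), .groups = "drop")
  manifest <- list(
    package_version = as.character(utils::packageVersion("cylsfm")),
    seed = seed,
    window = window,
    min_correct = min_correct,
    group_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, scores = scores, report = report,
                 manifest = manifest, out_dir = out_dir))
}
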
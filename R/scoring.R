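# ---- percept extraction -----------------------------------------------------

# collapse same-direction repeats; returns times/keys of the distinct reports
.distinct_reports <- function(t, key) {
  n <- length(t)
  if (n == 0) return(list(t = numeric(0), key = character(0)))
  keep <- c(TRUE, key[-1] != key[-n])
  list(t = t[keep], key = key[keep])
}

.check_events <- function(events, block_duration) {
  if (!all(c("t", "key") %in% names(events))) {
    abort("`events` must have columns `t` and `key`.")
  }
  if (is.unsorted(events$t)) abort("`events` must be sorted by time.")
  if (nrow(events) && (min(events$t) < 0 || max(events$t) > block_duration)) {
    abort("event times must lie within [0, block_duration].")
  }
  bad <- setdiff(unique(events$key), .directions)
  if (length(bad)) abort(sprintf("invalid key value(s): %s",
                                 paste(bad, collapse = ", ")))
  invisible(events)
}

#' Extract percept dominance intervals from a keypress stream
#'
#' The first keypress opens the first percept interval; every subsequent
#' keypress reporting a *different* direction closes the current interval and
#' opens the next (same-direction repeats report no new percept and are
#' ignored). The final interval, cut off by the block end rather than by a
#' reported switch, is returned flagged `censored = TRUE`; its length is
#' truncation-biased and is excluded from duration summaries. Percept
#' durations are therefore defined only after the observer's initial
#' response.
#'
#' @param events A data frame of keypresses with columns `t` (seconds,
#'   sorted) and `key` (`"left"`/`"right"`).
#' @param block_duration Block length in seconds (default 120).
#' @return A tibble of intervals: `start`, `end`, `duration`, `direction`,
#'   `censored`. Empty input gives an empty tibble.
#' @examples
#' ev <- tibble::tibble(t = c(2, 10, 25), key = c("left", "right", "left"))
#' extract_percepts(ev, 120)
#' @export
extract_percepts <- function(events, block_duration = 120) {
  .check_events(events, block_duration)
  d <- .distinct_reports(events$t, events$key)
  m <- length(d$t)
  if (m == 0) {
    return(tibble::tibble(start = double(), end = double(),
                          duration = double(), direction = character(),
                          censored = logical()))
  }
  start <- d$t
  end <- c(d$t[-1], block_duration)
  tibble::tibble(
    start = start, end = end, duration = end - start,
    direction = d$key,
    censored = c(rep(FALSE, m - 1), TRUE)
  )
}

#' Count reported perceptual switches in a keypress stream
#'
#' A switch is a direction *change* in the reported stream; the initial
#' report is not a switch and same-direction repeats are ignored.
#'
#' @inheritParams extract_percepts
#' @return Integer switch count.
#' @examples
#' count_switches(tibble::tibble(t = c(2, 10, 25),
#'                               key = c("left", "right", "left")))
#' @export
count_switches <- function(events) {
  if (is.unsorted(events$t)) abort("`events` must be sorted by time.")
  d <- .distinct_reports(events$t, events$key)
  max(length(d$t) - 1L, 0L)
}

#' Per-block switch rate with the zero-count replacement rule
#'
#' `switch_rate = n / block_duration`. Because a block with no reported
#' switches has rate 0 Hz (log10 of which is -Inf), zero counts are replaced
#' with 0.5 switches per block *for the log transform only*: `log10_rate =
#' log10(max(n, 0.5) / block_duration)`. The stored linear rate keeps the
#' true 0.
#'
#' @param n_switches Switch count(s) (vectorised, non-negative).
#' @param block_duration Block length in seconds.
#' @return A tibble with `n_switches`, `switch_rate` (Hz), `log10_rate`.
#' @examples
#' block_switch_rate(c(24, 0, 11))
#' @export
block_switch_rate <- function(n_switches, block_duration = 120) {
  if (any(n_switches < 0)) abort("`n_switches` must be non-negative.")
  .assert_scalar_num(block_duration, "block_duration", lower = 0,
                     strict_lower = TRUE)
  tibble::tibble(
    n_switches = n_switches,
    switch_rate = n_switches / block_duration,
    log10_rate = log10(pmax(n_switches, 0.5) / block_duration)
  )
}

# ---- real-switch scoring ----------------------------------------------------

#' Score a real-switch block against its physical schedule
#'
#' A response is correct for a physical switch if it reports the post-switch
#' direction and arrives within `window` seconds *after* the switch
#' (anticipations are never credited). Each physical switch is credited at
#' most once, by the earliest subsequent eligible response, and each response
#' is consumed by at most one switch (greedy one-to-one matching in time
#' order, which is optimal for interval-eligibility matching). Observers with
#' fewer than `min_correct` credited switches (default 7 of 11, i.e. an
#' accuracy at or below 63.6%) are flagged for exclusion.
#'
#' @inheritParams extract_percepts
#' @param schedule A [real_switch_schedule()].
#' @param window Credit window in seconds after each switch (default 4).
#' @param min_correct Inclusion threshold on credited switches (default 7).
#' @return A one-row tibble: `n_physical`, `n_correct`, `accuracy`,
#'   `mean_rt_correct` (credited responses), `mean_rt_uncapped` (nearest
#'   correct-direction response per switch, no window), `n_responses`,
#'   `included`.
#' @examples
#' sched <- real_switch_schedule()
#' ev <- tibble::tibble(t = c(0.6, sched$switch_times + 1),
#'                      key = c(sched$directions))
#' score_real_switch(ev, sched)
#' @export
score_real_switch <- function(events, schedule, window = 4, min_correct = 7) {
  stopifnot(inherits(schedule, "switch_schedule"))
  .check_events(events, schedule$block_duration)
  st <- schedule$switch_times
  post <- schedule$directions[-1]
  n_phys <- length(st)

  consumed <- rep(FALSE, nrow(events))
  credited_rt <- rep(NA_real_, n_phys)
  uncapped_rt <- rep(NA_real_, n_phys)
  for (i in seq_len(n_phys)) {
    lat <- events$t - st[i]
    ok_dir <- events$key == post[i] & lat > 0
    cand_any <- which(ok_dir & !consumed)
    if (length(cand_any)) uncapped_rt[i] <- lat[cand_any[1]]
    cand <- which(ok_dir & lat < window & !consumed)
    if (length(cand)) {
      j <- cand[1]                      # earliest eligible response
      consumed[j] <- TRUE
      credited_rt[i] <- lat[j]
    }
  }
  n_correct <- sum(!is.na(credited_rt))
  tibble::tibble(
    n_physical = n_phys,
    n_correct = n_correct,
    accuracy = n_correct / n_phys,
    mean_rt_correct = if (n_correct) mean(credited_rt, na.rm = TRUE) else NA_real_,
    mean_rt_uncapped = if (any(!is.na(uncapped_rt)))
      mean(uncapped_rt, na.rm = TRUE) else NA_real_,
    n_responses = nrow(events),
    included = n_correct >= min_correct
  )
}

# ---- block and subject summaries -------------------------------------------

# metrics for one block given its events (already a list of t/key vectors)
.block_metrics_one <- function(t, key, block_duration) {
  d <- .distinct_reports(t, key)
  m <- length(d$t)
  n_sw <- max(m - 1L, 0L)
  durations <- if (m >= 2) diff(d$t) else numeric(0)
  pre <- if (m >= 1) d$t[1] else block_duration
  censored <- if (m >= 1) block_duration - d$t[m] else 0
  list(n_switches = n_sw, durations = durations,
       pre_response = pre, censored_tail = censored)
}

#' Score every block and session of a cohort
#'
#' Runs the full behavioral analysis over a cohort's keypress event tables:
#' real-switch accuracy and inclusion screening, per-block bi-stable switch
#' rates (log10 scale with the zero-replacement rule), percept-duration
#' extraction, and per-subject-session summaries (mean log10 rate across
#' bi-stable blocks, pooled mean percept duration, and the coefficient of
#' variation sd/mean of percept durations, per task type).
#'
#' @param cohort An `sfm_cohort` with event tables, or a data frame of events
#'   (columns `subject_id`, `session`, `block`, `block_type`, `t`, `key`).
#' @param schedule The physical [real_switch_schedule()] (taken from the
#'   cohort when one is supplied).
#' @param window,min_correct Real-switch scoring parameters (4 s, 7).
#' @param block_duration Block length in seconds.
#' @return An object of class `sfm_scores`: list of tibbles `blocks` (one row
#'   per block with counts, rates and conservation components), `durations`
#'   (long, completed percept durations), and `subjects` (one row per
#'   subject-session with accuracy, inclusion, and bi-stable summaries).
#' @examples
#' spec <- cohort_spec(n_per_group = c(control = 3, relative = 3, pwpp = 3),
#'                     seed = 5)
#' sc <- score_cohort(simulate_cohort(spec))
#' sc$subjects
#' @export
score_cohort <- function(cohort, schedule = NULL, window = 4, min_correct = 7,
                         block_duration = 120) {
  if (inherits(cohort, "sfm_cohort")) {
    if (is.null(cohort$events)) {
      abort("this cohort was generated with `events = FALSE`; use `bistable_rate_metrics()` or regenerate with events.")
    }
    events <- cohort$events
    schedule <- schedule %||% cohort$schedule
    block_duration <- cohort$params$block_duration
  } else {
    events <- cohort
  }
  stopifnot(all(c("subject_id", "session", "block", "block_type", "t", "key")
                %in% names(events)))

  key_id <- paste(events$subject_id, events$session, events$block, sep = "\r")
  split_idx <- split(seq_len(nrow(events)), key_id)
  meta <- do.call(rbind, strsplit(names(split_idx), "\r", fixed = TRUE))
  btype <- vapply(split_idx, function(ix) events$block_type[ix[1]],
                  character(1))

  per_block <- lapply(split_idx, function(ix) {
    .block_metrics_one(events$t[ix], events$key[ix], block_duration)
  })
  names(per_block) <- NULL
  ndur <- vapply(per_block, function(b) length(b$durations), integer(1))
  nsw <- vapply(per_block, function(b) b$n_switches, numeric(1))

  blocks <- tibble::tibble(
    subject_id = meta[, 1],
    session = as.integer(meta[, 2]),
    block = as.integer(meta[, 3]),
    block_type = btype,
    n_switches = as.integer(nsw),
    switch_rate = nsw / block_duration,
    log10_rate = log10(pmax(nsw, 0.5) / block_duration),
    n_durations = ndur,
    mean_duration = vapply(per_block, function(b) {
      if (length(b$durations)) mean(b$durations) else NA_real_
    }, numeric(1)),
    pre_response = vapply(per_block, function(b) b$pre_response, numeric(1)),
    censored_tail = vapply(per_block, function(b) b$censored_tail, numeric(1)),
    sum_durations = vapply(per_block, function(b) sum(b$durations), numeric(1))
  ) |>
    dplyr::arrange(.data$subject_id, .data$session, .data$block)

  durations <- tibble::tibble(
    subject_id = rep(meta[, 1], times = ndur),
    session = as.integer(rep(meta[, 2], times = ndur)),
    block = as.integer(rep(meta[, 3], times = ndur)),
    block_type = rep(btype, times = ndur),
    duration = unlist(lapply(per_block, function(b) b$durations),
                      use.names = FALSE)
  )

  # real-switch scoring per session
  rs <- events[events$block_type == "real_switch", , drop = FALSE]
  rs_scores <- if (nrow(rs) && !is.null(schedule)) {
    rs |>
      dplyr::group_by(.data$subject_id, .data$session) |>
      dplyr::group_modify(~ score_real_switch(.x, schedule, window,
                                              min_correct)) |>
      dplyr::ungroup()
  } else {
    NULL
  }

  subjects <- blocks |>
    dplyr::filter(.data$block_type == "bistable") |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(
      n_bistable_blocks = dplyr::n(),
      mean_log10_rate = mean(.data$log10_rate),
      mean_rate = mean(.data$switch_rate),
      .groups = "drop"
    )
  dsum <- durations |>
    dplyr::group_by(.data$subject_id, .data$session, .data$block_type) |>
    dplyr::summarise(
      mean_duration = mean(.data$duration),
      cv = ifelse(mean(.data$duration) > 0,
                  sd(.data$duration) / mean(.data$duration), NA_real_),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "block_type",
      values_from = c("mean_duration", "cv"),
      names_glue = "{block_type}_{.value}"
    )
  subjects <- dplyr::left_join(subjects, dsum,
                               by = c("subject_id", "session"))
  if (!is.null(rs_scores)) {
    subjects <- dplyr::left_join(subjects, rs_scores,
                                 by = c("subject_id", "session"))
  } else {
    subjects$included <- TRUE        # real-switch stage bypassed
    inform("no real-switch blocks found: inclusion screening bypassed, all sessions included.")
  }

  structure(
    list(blocks = blocks, durations = durations, subjects = subjects,
         window = window, min_correct = min_correct,
         block_duration = block_duration),
    class = "sfm_scores"
  )
}

#' @export
print.sfm_scores <- function(x, ...) {
  cat("<sfm_scores>\n")
  cat(sprintf("  %d blocks, %d sessions (%d included), %d percept durations\n",
              nrow(x$blocks), nrow(x$subjects), sum(x$subjects$included),
              nrow(x$durations)))
  invisible(x)
}

#' Summarise one session's scored blocks
#'
#' Per-subject summary of a single session from tidy block metrics and
#' durations, as used inside [score_cohort()]: mean of the per-block log10
#' switch rates over the bi-stable blocks, pooled mean percept duration, and
#' the coefficient of variation of percept durations.
#'
#' @param blocks A tibble of bi-stable block metrics (columns `log10_rate`,
#'   `switch_rate`; one row per block).
#' @param durations Numeric vector of completed percept durations.
#' @return A one-row tibble: `n_bistable_blocks`, `mean_log10_rate`,
#'   `mean_rate`, `mean_duration`, `cv`.
#' @examples
#' subject_metrics(block_switch_rate(c(20, 25, 22, 24, 21)),
#'                 durations = rgamma(50, 4, 1))
#' @export
subject_metrics <- function(blocks, durations = numeric(0)) {
  if (nrow(blocks) == 0) abort("at least one bi-stable block is required.")
  tibble::tibble(
    n_bistable_blocks = nrow(blocks),
    mean_log10_rate = mean(blocks$log10_rate),
    mean_rate = mean(blocks$switch_rate),
    mean_duration = if (length(durations)) mean(durations) else NA_real_,
    cv = if (length(durations) > 1 && mean(durations) > 0)
      sd(durations) / mean(durations) else NA_real_
  )
}

#' @rdname sfm_tidiers
#' @export
tidy.sfm_scores <- function(x, ...) x$subjects

#' @rdname sfm_tidiers
#' @export
glance.sfm_scores <- function(x, ...) {
  tibble::tibble(
    n_sessions = nrow(x$subjects),
    n_included = sum(x$subjects$included),
    n_blocks = nrow(x$blocks),
    n_durations = nrow(x$durations),
    mean_log10_rate = mean(x$subjects$mean_log10_rate)
  )
}
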
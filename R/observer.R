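# ---- low-level renewal simulation ------------------------------------------
#
# All bi-stable streams in a cohort are drawn by one call to
# .sim_bistable_streams() so that the event-level and count-level generation
# paths consume the identical RNG stream and agree bit-for-bit.

# onset latency: lognormal with the requested mean and sdlog 0.5
.sim_latencies <- function(n, mean) {
  rlnorm(n, meanlog = log(mean) - 0.125, sdlog = 0.5)
}

# gamma-renewal percept switch epochs for many blocks at once.
# scales: per-block gamma scale (seconds). Returns latencies, initial
# directions and a list of switch-epoch vectors (times in (latency, duration)).
.sim_bistable_streams <- function(scales, shape, latency_mean, duration) {
  nb <- length(scales)
  latencies <- .sim_latencies(nb, latency_mean)
  d0 <- sample(.directions, nb, replace = TRUE)

  mean_dur <- shape * scales
  exp_n <- duration / mean_dur
  k <- max(5L, ceiling(max(exp_n + 6 * sqrt(exp_n / shape)) + 5))
  g <- rgamma(nb * k, shape = shape, scale = rep(scales, each = k))
  cs <- cumsum(g)
  offsets <- c(0, cs[k * seq_len(nb - 1)])
  cum <- cs - rep(offsets, each = k)                    # per-block cumsum
  epoch <- rep(latencies, each = k) + cum

  dim(epoch) <- c(k, nb)
  budget <- duration - latencies
  short <- which(cum[k * seq_len(nb)] < budget)         # rare: top up
  extra <- vector("list", nb)
  for (b in short) {
    tail_t <- epoch[k, b]
    more <- numeric(0)
    while (tail_t < duration) {
      add <- rgamma(k, shape = shape, scale = scales[b])
      more <- c(more, tail_t + cumsum(add))
      tail_t <- more[length(more)]
    }
    extra[[b]] <- more
  }
  epochs <- lapply(seq_len(nb), function(b) {
    e <- c(epoch[, b], extra[[b]])
    e[e < duration & latencies[b] < duration]
  })
  list(latency = latencies, first_direction = d0, epochs = epochs)
}

# encode one stream (onset report + alternating switch reports) as keypresses
.stream_to_events <- function(latency, first_direction, epochs, duration) {
  if (latency >= duration) {
    return(list(t = numeric(0), key = character(0)))
  }
  t <- c(latency, epochs)
  flips <- seq_along(t) - 1L
  key <- ifelse(flips %% 2 == 0, first_direction,
                .other_direction(first_direction))
  list(t = t, key = key)
}

#' Simulate keypresses for one bi-stable block
#'
#' The observer reports the initial percept after a lognormal onset latency
#' and thereafter alternates percepts at gamma-renewal epochs
#' (`Gamma(gamma_shape, gamma_scale)` dominance durations), truncated at the
#' block end. A latency longer than the block legally yields zero keypresses.
#'
#' @param observer An [observer_params()] object.
#' @param duration Block duration in seconds (default 120).
#' @param seed Integer seed; identical seeds give identical event streams.
#' @return A tibble of keypress events: `t` (s), `key` (`"left"`/`"right"`).
#' @examples
#' simulate_bistable_block(observer_params(), seed = 7)
#' @export
simulate_bistable_block <- function(observer, duration = 120, seed = 1L) {
  stopifnot(inherits(observer, "observer_params"))
  .assert_scalar_num(duration, "duration", lower = 0, strict_lower = TRUE)
  set.seed(.child_seed(seed, "bistable-block"))
  s <- .sim_bistable_streams(observer$gamma_scale, observer$gamma_shape,
                             observer$initial_latency_mean, duration)
  ev <- .stream_to_events(s$latency, s$first_direction, s$epochs[[1]], duration)
  tibble::tibble(t = ev$t, key = ev$key)
}

# real-switch response stream for one block; RNG is taken from the current
# stream (callers seed it)
.sim_real_switch_events <- function(observer, schedule) {
  dur <- schedule$block_duration
  st <- schedule$switch_times
  post_dir <- schedule$directions[-1]
  n <- length(st)

  onset_t <- .sim_latencies(1, observer$initial_latency_mean)
  onset_err <- runif(1) < observer$error_prob
  onset_key <- if (onset_err) .other_direction(schedule$directions[1]) else
    schedule$directions[1]

  missed <- runif(n) < observer$miss_prob
  rts <- rlnorm(n, meanlog = observer$rt_mu, sdlog = observer$rt_sigma)
  errs <- runif(n) < observer$error_prob
  resp_t <- st + rts
  resp_key <- ifelse(errs, .other_direction(post_dir), post_dir)
  keep <- !missed & resp_t < dur

  n_sp <- rpois(1, observer$spontaneous_rate * dur)
  sp_t <- sort(runif(n_sp, 0, dur))
  # illusory reversal: reports the opposite of the physical direction
  sp_key <- .other_direction(.direction_at(schedule, sp_t))

  t <- c(onset_t, resp_t[keep], sp_t)
  key <- c(onset_key, resp_key[keep], sp_key)
  o <- order(t)
  in_block <- t[o] < dur
  list(t = t[o][in_block], key = key[o][in_block])
}

#' Simulate keypresses for one real-switch block
#'
#' The observer reports the initial physical direction shortly after onset;
#' each scheduled physical reversal is reported with probability
#' `1 - miss_prob` after a lognormal reaction time (wrong direction with
#' probability `error_prob`); spontaneous illusory reversal reports are
#' superimposed as a Poisson process.
#'
#' @inheritParams simulate_bistable_block
#' @param schedule A [real_switch_schedule()] object.
#' @return A tibble of keypress events: `t`, `key`.
#' @examples
#' sched <- real_switch_schedule()
#' simulate_real_switch_block(observer_params(), sched, seed = 3)
#' @export
simulate_real_switch_block <- function(observer, schedule, seed = 1L) {
  stopifnot(inherits(observer, "observer_params"),
            inherits(schedule, "switch_schedule"))
  set.seed(.child_seed(seed, "real-switch-block"))
  ev <- .sim_real_switch_events(observer, schedule)
  tibble::tibble(t = ev$t, key = ev$key)
}

# ---- cohort generation ------------------------------------------------------

#' Simulate a synthetic observer cohort
#'
#' Generates a three-group cohort of synthetic observers according to a
#' [cohort_spec()]: per-subject log10 switch rates (a stable subject effect
#' plus session-level noise calibrated to the target test-retest ICC),
#' per-block gamma-renewal keypress streams for the five bi-stable blocks,
#' one real-switch block per session scored against the canonical physical
#' schedule, and clinical/metabolite covariates rank-coupled to the
#' session-1 switch rate through a Gaussian copula.
#'
#' With `events = FALSE` the generator draws the identical renewal epochs
#' (same RNG sub-streams, so per-block switch counts match the event path
#' exactly) but skips keypress-table assembly and the real-switch blocks;
#' this count-level path is the fast route for replicate-heavy calibration
#' studies, and [bistable_rate_metrics()] turns its counts into the same
#' rate metrics that scoring the events would produce.
#'
#' @param spec A [cohort_spec()].
#' @param params A [cylinder_params()] (block duration, canonical schedule).
#' @param events If `TRUE` (default) build full keypress event tables.
#' @return An object of class `sfm_cohort`: a list with `sessions` (one row
#'   per subject-session: group, covariates, metabolites, flags),
#'   `bistable_counts` (per-block reported switch counts), `events` (tibble
#'   or `NULL`), `schedule`, `spec`, `params`.
#' @examples
#' spec <- cohort_spec(n_per_group = c(control = 4, relative = 4, pwpp = 4),
#'                     seed = 11)
#' coh <- simulate_cohort(spec)
#' dplyr::count(coh$sessions, group, session)
#' @export
simulate_cohort <- function(spec, params = cylinder_params(), events = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  obs <- spec$observer
  npg <- spec$n_per_group
  n <- sum(npg)
  if (n < 2) abort("a cohort needs at least 2 subjects.")
  groups <- factor(rep(names(npg), times = npg),
                   levels = c("control", "relative", "pwpp"))
  if (any(npg == 0)) {
    warn(sprintf("empty group(s): %s; downstream group statistics will use %d groups.",
                 paste(names(npg)[npg == 0], collapse = ", "),
                 sum(npg > 0)))
  }
  subject_id <- sprintf("S%04d", seq_len(n))
  mu <- .group_means(spec)[as.character(groups)]
  vv <- .icc_variances(spec$group_log10_rate_sd, spec$retest_icc, k = 2)

  ## stage 1: subject-level draws -------------------------------------------
  set.seed(.child_seed(spec$seed, "subjects"))
  theta <- mu + rnorm(n, 0, sqrt(vv["vb"]))
  eps1 <- rnorm(n, 0, sqrt(vv["ve"]))
  eps2 <- rnorm(n, 0, sqrt(vv["ve"]))
  miss_prob <- if (is.finite(spec$miss_prob_kappa) && obs$miss_prob > 0 &&
                   obs$miss_prob < 1) {
    kap <- spec$miss_prob_kappa
    rbeta(n, obs$miss_prob * kap, (1 - obs$miss_prob) * kap)
  } else {
    rep(obs$miss_prob, n)
  }
  benzo <- runif(n) < spec$benzodiazepine_prob[as.character(groups)]

  # Gaussian copula: couple each covariate to the session-1 latent log10 rate
  eta1 <- theta + eps1
  z <- as.numeric(scale(eta1))
  cov_tab <- spec$covariates
  cov_vals <- purrr::pmap(cov_tab, function(covariate, rho, mean, sd, kind) {
    rho_p <- 2 * sin(pi * rho / 6)         # latent Pearson for Spearman target
    u <- rho_p * z + sqrt(1 - rho_p^2) * rnorm(n)
    mean + sd * u
  })
  names(cov_vals) <- cov_tab$covariate

  retest <- unlist(lapply(names(npg), function(g) {
    ng <- npg[[g]]
    c(rep(TRUE, round(spec$retest_fraction * ng)),
      rep(FALSE, ng - round(spec$retest_fraction * ng)))
  }))

  sessions <- tibble::tibble(
    subject_id = rep(subject_id, times = 1 + retest),
    group = rep(groups, times = 1 + retest),
    session = unlist(lapply(retest, function(r) seq_len(1 + r))),
    benzodiazepine = rep(benzo, times = 1 + retest)
  )
  sessions$latent_log10_rate <- ifelse(sessions$session == 1,
                                       rep(theta + eps1, times = 1 + retest),
                                       rep(theta + eps2, times = 1 + retest))
  for (cv in names(cov_vals)) {
    sessions[[cv]] <- rep(cov_vals[[cv]], times = 1 + retest)
  }
  sessions$miss_prob <- rep(miss_prob, times = 1 + retest)

  ## stage 2: bi-stable blocks ----------------------------------------------
  nb <- spec$n_bistable_blocks
  dur <- params$block_duration
  block_index <- seq_len(nb)
  blocks <- sessions[rep(seq_len(nrow(sessions)), each = nb),
                     c("subject_id", "session", "latent_log10_rate")]
  blocks$bistable_block <- rep(block_index, times = nrow(sessions))
  # centre the block drift so the session mean rate is unchanged
  blocks$log10_rate_blk <- blocks$latent_log10_rate +
    spec$block_log10_slope * (blocks$bistable_block - (nb + 1) / 2)
  scales <- 1 / (obs$gamma_shape * 10^blocks$log10_rate_blk)

  set.seed(.child_seed(spec$seed, "bistable"))
  streams <- .sim_bistable_streams(scales, obs$gamma_shape,
                                   obs$initial_latency_mean, dur)
  n_switch <- lengths(streams$epochs)
  zero_stream <- streams$latency >= dur
  counts <- tibble::tibble(
    subject_id = blocks$subject_id,
    session = blocks$session,
    block = blocks$bistable_block + 1L,      # block 1 is the real-switch block
    block_type = "bistable",
    n_switches = ifelse(zero_stream, 0L, n_switch),
    latency = streams$latency
  )

  events_tbl <- NULL
  if (events) {
    ev_bis <- purrr::map(seq_len(nrow(blocks)), function(b) {
      .stream_to_events(streams$latency[b], streams$first_direction[b],
                        streams$epochs[[b]], dur)
    })
    nev <- vapply(ev_bis, function(e) length(e$t), integer(1))
    bis_events <- tibble::tibble(
      subject_id = rep(blocks$subject_id, times = nev),
      session = rep(blocks$session, times = nev),
      block = rep(blocks$bistable_block + 1L, times = nev),
      block_type = "bistable",
      t = unlist(lapply(ev_bis, `[[`, "t")),
      key = unlist(lapply(ev_bis, `[[`, "key"))
    )

    ## stage 3: real-switch blocks ------------------------------------------
    schedule <- real_switch_schedule(params, seed = "paper")
    set.seed(.child_seed(spec$seed, "realswitch"))
    rs <- purrr::map(seq_len(nrow(sessions)), function(i) {
      o <- obs
      o$miss_prob <- sessions$miss_prob[i]
      .sim_real_switch_events(o, schedule)
    })
    nrs <- vapply(rs, function(e) length(e$t), integer(1))
    rs_events <- tibble::tibble(
      subject_id = rep(sessions$subject_id, times = nrs),
      session = rep(sessions$session, times = nrs),
      block = 1L,
      block_type = "real_switch",
      t = unlist(lapply(rs, `[[`, "t")),
      key = unlist(lapply(rs, `[[`, "key"))
    )
    events_tbl <- dplyr::arrange(
      dplyr::bind_rows(rs_events, bis_events),
      .data$subject_id, .data$session, .data$block, .data$t
    )
  } else {
    schedule <- real_switch_schedule(params, seed = "paper")
  }

  structure(
    list(
      sessions = sessions,
      bistable_counts = counts,
      events = events_tbl,
      schedule = schedule,
      spec = spec,
      params = params
    ),
    class = "sfm_cohort"
  )
}

#' @export
print.sfm_cohort <- function(x, ...) {
  cat("<sfm_cohort>\n")
  cat(sprintf("  %d subjects, %d sessions, %d bi-stable blocks%s\n",
              dplyr::n_distinct(x$sessions$subject_id), nrow(x$sessions),
              nrow(x$bistable_counts),
              if (is.null(x$events)) " (count-level, no event tables)" else ""))
  invisible(x)
}

#' Bi-stable rate metrics straight from a cohort's switch counts
#'
#' Computes per-block switch rates (with the zero-count replacement rule of
#' [block_switch_rate()]) and per-session mean log10 rates directly from the
#' generator's per-block reported switch counts, without scoring keypress
#' event tables. For the same seed this matches [score_cohort()]'s bi-stable
#' rate metrics exactly, because both paths share the same renewal draws.
#'
#' @param cohort An `sfm_cohort`.
#' @return A tibble, one row per subject-session: `subject_id`, `group`,
#'   `session`, `mean_log10_rate`, `mean_rate`.
#' @export
bistable_rate_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "sfm_cohort"))
  dur <- cohort$params$block_duration
  cohort$bistable_counts |>
    dplyr::mutate(
      log10_rate = log10(pmax(.data$n_switches, 0.5) / dur),
      rate = .data$n_switches / dur
    ) |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(
      mean_log10_rate = mean(.data$log10_rate),
      mean_rate = mean(.data$rate),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::distinct(cohort$sessions, .data$subject_id, .data$group),
      by = "subject_id"
    ) |>
    dplyr::relocate("group", .after = "subject_id")
}
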
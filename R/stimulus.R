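#' Horizontal dot position on the rotating cylinder
#'
#' Projects uniform circular motion onto the screen plane: a dot at initial
#' angular position `phase0` on a cylinder of radius `width / 2` rotating at
#' `rotation_speed` degrees per second has horizontal position
#' `x(t) = (width / 2) * sin(omega * t + phase0)` with `omega` the rotation
#' speed in radians per second. Horizontal speed is maximal at the aperture
#' midline (x = 0) and falls to zero at the edges, the signature of
#' structure-from-motion cylinder stimuli.
#'
#' @param t Time in seconds (vectorised, `t >= 0`).
#' @param phase0 Initial angular position in radians.
#' @param params A [cylinder_params()] object.
#' @return Horizontal position(s) in degrees of visual angle.
#' @examples
#' p <- cylinder_params()
#' dot_x(0, 0, p)            # midline
#' dot_x(1, 0, p)            # 90 deg later: at the right edge, x = 3.5
#' @export
dot_x <- function(t, phase0, params = cylinder_params()) {
  if (!is.numeric(t) || any(!is.finite(t))) abort("`t` must be finite numeric.")
  if (any(t < 0)) abort("`t` must be non-negative.")
  omega <- params$rotation_speed * pi / 180
  (params$width / 2) * sin(omega * t + phase0)
}

#' Generate rotating-cylinder dot trajectories
#'
#' Draws the dot field (heights pseudo-random along the aperture, initial
#' phases uniform, the two counter-phase surfaces paired at a phase offset of
#' pi) and samples each dot's horizontal position at the stimulus frame rate
#' over `duration` seconds.
#'
#' @param params A [cylinder_params()] object.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param duration Sampled duration in seconds (defaults to
#'   `params$block_duration`).
#' @return A tibble with one row per dot and frame: `dot_id`, `frame`
#'   (0-based), `t` (s), `x`, `y` (deg), `polarity` (`"black"`/`"white"`),
#'   `surface` (1 or 2), `phase0` (rad).
#' @examples
#' traj <- generate_trajectories(cylinder_params(n_dots = 4), seed = 1,
#'                               duration = 4)
#' range(traj$x)   # bounded by +/- width / 2
#' @export
generate_trajectories <- function(params = cylinder_params(), seed = 1L,
                                  duration = params$block_duration) {
  n <- params$n_dots
  if (n == 0) {
    warn("`n_dots` is 0: returning an empty trajectory table.")
    return(tibble::tibble(
      dot_id = integer(), frame = integer(), t = double(), x = double(),
      y = double(), polarity = character(), surface = integer(),
      phase0 = double()
    ))
  }
  if (n %% 2 != 0) abort("`n_dots` must be even (two paired surfaces).")
  set.seed(.child_seed(seed, "trajectories"))
  half <- n %/% 2
  phase1 <- runif(half, 0, 2 * pi)
  phase0 <- c(phase1, phase1 + pi)           # surface 2 in counterphase
  surface <- rep(1:2, each = half)
  y <- runif(n, -params$height / 2, params$height / 2)
  polarity <- sample(rep(c("black", "white"),
                         times = c(params$n_black, params$n_white)))

  n_frames <- floor(duration * params$frame_rate) + 1L
  t <- (seq_len(n_frames) - 1L) / params$frame_rate
  omega <- params$rotation_speed * pi / 180
  r <- params$width / 2

  # outer(): frames vary fastest within dot
  x <- as.vector(r * sin(outer(t, phase0, function(tt, p0) omega * tt + p0)))
  tibble::tibble(
    dot_id = rep(seq_len(n), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = n),
    t = rep(t, times = n),
    x = x,
    y = rep(y, each = n_frames),
    polarity = rep(polarity, each = n_frames),
    surface = rep(surface, each = n_frames),
    phase0 = rep(phase0, each = n_frames)
  )
}

#' Recover the angular rotation speed from sampled trajectories
#'
#' For each dot, unwraps the angular phase `asin(x / R)` (with the branch
#' chosen from the sign of the sampled horizontal velocity, then made
#' continuous across full turns) and regresses it on time; the slope is the
#' angular speed. Returns per-dot fits and the across-dot median, which for
#' noiseless generated trajectories recovers the configured rotation speed.
#'
#' @param trajectories A tibble as produced by [generate_trajectories()].
#' @param params The [cylinder_params()] used to generate them (supplies the
#'   cylinder radius `width / 2`).
#' @return A list with `per_dot` (tibble: `dot_id`, `omega_deg_s`) and
#'   `omega_deg_s`, the median fitted speed in degrees per second.
#' @examples
#' p <- cylinder_params(n_dots = 10)
#' fit <- fit_angular_speed(generate_trajectories(p, seed = 2, duration = 8), p)
#' fit$omega_deg_s
#' @export
fit_angular_speed <- function(trajectories, params = cylinder_params()) {
  r <- params$width / 2
  fits <- trajectories |>
    dplyr::group_by(.data$dot_id) |>
    dplyr::summarise(
      omega_deg_s = .fit_omega_one(.data$t, .data$x, r),
      .groups = "drop"
    )
  list(per_dot = fits, omega_deg_s = median(fits$omega_deg_s, na.rm = TRUE))
}

# unwrapped-arcsine phase regression for a single dot
.fit_omega_one <- function(t, x, r) {
  if (length(t) < 3) return(NA_real_)
  s <- asin(pmin(1, pmax(-1, x / r)))
  dx <- diff(x)
  ascending <- c(dx >= 0, TRUE)             # sign of cos(theta)
  theta <- ifelse(ascending, s, pi - s)
  # make the phase monotone: close each wrap of 2*pi
  d <- diff(theta)
  jump <- cumsum(c(0, ifelse(d < -pi, 2 * pi, ifelse(d > pi, -2 * pi, 0))))
  theta <- theta + jump
  slope <- stats::cov(t, theta) / stats::var(t)
  slope * 180 / pi
}

#' Physical switch schedule for the real-switch task
#'
#' Builds the timeline of physical rotation-direction reversals used in the
#' real-switch control block: 11 switches in a 120-s block, inter-switch
#' intervals drawn from {9, 11, 13} s (so the 9-13 s range is respected and
#' the mean physical switch rate is 11/120 = 0.09 Hz), directions strictly
#' alternating. `seed = "paper"` returns the fixed canonical schedule shipped
#' for reproducibility; an integer seed draws a pseudo-random feasible
#' schedule (rejection sampling until all switches fit inside the block).
#'
#' @param params A [cylinder_params()] object (`block_duration` is used).
#' @param seed `"paper"` for the canonical fixed schedule, or an integer.
#' @param n_switches Number of physical switches (default 11).
#' @param intervals Allowed inter-switch intervals in seconds.
#' @param initial_direction Front-surface direction of the first segment.
#' @return An object of class `switch_schedule`: a list with
#'   `block_duration`, `switch_times` (length `n_switches`), and `directions`
#'   (length `n_switches + 1`, the initial direction first).
#' @examples
#' sched <- real_switch_schedule()
#' length(sched$switch_times)
#' mean_physical_rate(sched)
#' @export
real_switch_schedule <- function(params = cylinder_params(), seed = "paper",
                                 n_switches = 11, intervals = c(9, 11, 13),
                                 initial_direction = "left") {
  dur <- params$block_duration
  if (min(intervals) * n_switches >= dur) {
    abort("requested switch intervals cannot fit inside the block.")
  }
  if (identical(seed, "paper")) {
    if (n_switches != 11 || dur != 120) {
      abort("the canonical schedule is defined for 11 switches in 120 s.")
    }
    gaps <- c(9, 11, 9, 13, 9, 11, 9, 13, 9, 11, 9)
  } else {
    set.seed(.child_seed(seed, "schedule"))
    repeat {
      gaps <- sample(intervals, n_switches, replace = TRUE)
      if (sum(gaps) < dur) break
    }
  }
  times <- cumsum(gaps)
  dirs <- rep(c(initial_direction, .other_direction(initial_direction)),
              length.out = n_switches + 1)
  structure(
    list(block_duration = dur, switch_times = times, directions = dirs),
    class = "switch_schedule"
  )
}

#' @export
print.switch_schedule <- function(x, ...) {
  cat("<switch_schedule>\n")
  cat(sprintf("  %d physical switches in %.4g s (mean rate %.3g Hz)\n",
              length(x$switch_times), x$block_duration,
              mean_physical_rate(x)))
  cat("  times:", paste(x$switch_times, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn real_switch_schedule Mean physical switch rate of a schedule
#'   (switches per second).
#' @param schedule A `switch_schedule`.
#' @export
mean_physical_rate <- function(schedule) {
  length(schedule$switch_times) / schedule$block_duration
}

#' Tidy a switch schedule into per-segment rows
#'
#' @param x A `switch_schedule`.
#' @param ... Unused.
#' @return A tibble with one row per segment: `segment`, `start`, `end`,
#'   `direction`.
#' @export
tidy.switch_schedule <- function(x, ...) {
  bounds <- c(0, x$switch_times, x$block_duration)
  tibble::tibble(
    segment = seq_along(x$directions),
    start = bounds[-length(bounds)],
    end = bounds[-1],
    direction = x$directions
  )
}

# physical front-surface direction at arbitrary times
.direction_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$switch_times) + 1L
  schedule$directions[idx]
}
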
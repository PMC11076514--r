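#' Rotating-cylinder stimulus parameters
#'
#' Geometry and timing of the structure-from-motion (SFM) rotating cylinder:
#' 400 black/white square dots span a 7 deg x 10 deg aperture and oscillate
#' horizontally with the sinusoidal speed profile of points on a transparent
#' cylinder rotating in depth at 90 deg/s. Two dot sheets (the front and back
#' "surfaces") move in counterphase.
#'
#' @param n_dots Total number of dots (default 400).
#' @param dot_size Dot side length, degrees of visual angle (default 0.25).
#' @param n_black,n_white Dot counts by polarity; must sum to `n_dots`.
#' @param width,height Aperture width and height in degrees (7, 10).
#' @param rotation_speed Simulated rotation speed, degrees of rotation per
#'   second (default 90).
#' @param fixation_diameter,cue_circle_diameter Fixation dot and depth-cue
#'   circle diameters, degrees (0.6, 1.8).
#' @param frame_rate Sampling rate of the generated trajectories, Hz
#'   (default 60).
#' @param block_duration Block length in seconds (default 120).
#'
#' @return An object of class `cylinder_params` (a named list).
#' @examples
#' p <- cylinder_params()
#' p$rotation_speed
#' @export
cylinder_params <- function(n_dots = 400, dot_size = 0.25,
                            n_black = n_dots / 2, n_white = n_dots / 2,
                            width = 7, height = 10, rotation_speed = 90,
                            fixation_diameter = 0.6, cue_circle_diameter = 1.8,
                            frame_rate = 60, block_duration = 120) {
  .assert_scalar_num(n_dots, "n_dots", lower = 0)
  .assert_scalar_num(width, "width", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(height, "height", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(rotation_speed, "rotation_speed", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(block_duration, "block_duration", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  if (n_black + n_white != n_dots) {
    abort("`n_black` + `n_white` must equal `n_dots`.")
  }
  structure(
    list(
      n_dots = as.integer(n_dots), dot_size = dot_size,
      n_black = as.integer(n_black), n_white = as.integer(n_white),
      width = width, height = height, rotation_speed = rotation_speed,
      fixation_diameter = fixation_diameter,
      cue_circle_diameter = cue_circle_diameter,
      frame_rate = frame_rate, block_duration = block_duration
    ),
    class = "cylinder_params"
  )
}

#' @export
print.cylinder_params <- function(x, ...) {
  cat("<cylinder_params>\n")
  cat(sprintf("  %d dots (%d black / %d white), %.2g x %.2g deg aperture\n",
              x$n_dots, x$n_black, x$n_white, x$width, x$height))
  cat(sprintf("  rotation %.3g deg/s, %.3g Hz sampling, %.4g s blocks\n",
              x$rotation_speed, x$frame_rate, x$block_duration))
  invisible(x)
}

#' Synthetic observer response parameters
#'
#' Generative model of a single observer. Bi-stable percept dominance
#' durations follow a gamma renewal process (`Gamma(gamma_shape,
#' gamma_scale)`, mean `gamma_shape * gamma_scale` seconds); the first
#' keypress reports the initial percept after a lognormal onset latency. In
#' real-switch blocks each physical direction change is reported with
#' probability `1 - miss_prob` after a lognormal reaction time
#' (`rt_mu`/`rt_sigma` on the log-seconds scale), with the wrong direction
#' reported with probability `error_prob`; additional spontaneous reversal
#' reports occur as a Poisson process with rate `spontaneous_rate`.
#'
#' @param gamma_shape Gamma shape of dominance durations (> 0; default 4,
#'   typical of bi-stable alternation statistics).
#' @param gamma_scale Gamma scale in seconds (> 0; default 2, i.e. a mean
#'   dominance duration of 8 s, approx. 0.125 switches/s).
#' @param initial_latency_mean Mean onset-response latency, seconds.
#' @param rt_mu,rt_sigma Lognormal reaction-time parameters (log-seconds).
#' @param miss_prob Probability a physical switch receives no response.
#' @param error_prob Probability a response reports the wrong direction.
#' @param spontaneous_rate Rate (Hz) of extra reversal reports during
#'   real-switch blocks.
#'
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(gamma_shape = 3, gamma_scale = 2.5)
#' @export
observer_params <- function(gamma_shape = 4, gamma_scale = 2,
                            initial_latency_mean = 1.5,
                            rt_mu = 0, rt_sigma = 0.4,
                            miss_prob = 0.12, error_prob = 0.02,
                            spontaneous_rate = 0.01) {
  .assert_scalar_num(gamma_shape, "gamma_shape", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(gamma_scale, "gamma_scale", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(initial_latency_mean, "initial_latency_mean",
                     lower = 0, strict_lower = TRUE)
  .assert_scalar_num(rt_sigma, "rt_sigma", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(miss_prob, "miss_prob", lower = 0, upper = 1)
  .assert_scalar_num(error_prob, "error_prob", lower = 0, upper = 1)
  .assert_scalar_num(spontaneous_rate, "spontaneous_rate", lower = 0)
  structure(
    list(
      gamma_shape = gamma_shape, gamma_scale = gamma_scale,
      initial_latency_mean = initial_latency_mean,
      rt_mu = rt_mu, rt_sigma = rt_sigma,
      miss_prob = miss_prob, error_prob = error_prob,
      spontaneous_rate = spontaneous_rate
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  durations ~ Gamma(shape = %.3g, scale = %.3g s)  mean %.3g s\n",
              x$gamma_shape, x$gamma_scale, x$gamma_shape * x$gamma_scale))
  cat(sprintf("  RT ~ lognormal(mu = %.3g, sigma = %.3g); miss %.2g, error %.2g\n",
              x$rt_mu, x$rt_sigma, x$miss_prob, x$error_prob))
  invisible(x)
}

# default rank-correlation targets between per-subject switch rate and each
# covariate / metabolite, with plausible clinical-scale marginals
.default_covariates <- function() {
  tibble::tribble(
    ~covariate,  ~rho,   ~mean, ~sd,   ~kind,
    "BPRS",       0.207,  35,    10,   "clinical",
    "SPQ",        0.188,  20,    12,   "clinical",
    "BACS",      -0.139,   0,     1,   "clinical",
    "SGI",        0.161,  60,    25,   "clinical",
    "BPRS_D",     0.264,   5,     2,   "clinical",
    "SPQ_CP",     0.209,   7,     5,   "clinical",
    "GABA",      -0.16,    1.5,   0.2, "metabolite",
    "glutamate", -0.058,   8.5,   0.9, "metabolite",
    "glutamine",  0.06,    2.4,   0.4, "metabolite"
  )
}

#' Cohort specification for the synthetic observer generator
#'
#' Describes a three-group cohort (healthy controls, first-degree biological
#' relatives, and people with psychotic psychopathology, "PwPP") of synthetic
#' observers. Per-subject switch rates are drawn on the log10 scale, the
#' analysis scale of the pipeline: the control group mean is
#' `control_log10_mean`, the PwPP mean sits `target_d` pooled standard
#' deviations above it (faster switching), and the relatives' mean lies at
#' `relative_position` of the way in between. The per-measurement standard
#' deviation `group_log10_rate_sd` is split into a stable subject effect and
#' session-level noise so that the two-session reliability equals
#' `retest_icc` (ICC(3,k), k = 2). Covariates and metabolite concentrations
#' are rank-coupled to the subject's session-1 switch rate through a Gaussian
#' copula at the Spearman targets in `covariates` (overridable for the two
#' headline targets through `symptom_rho` for the BPRS disorganization factor
#' and `gaba_rho` for occipital GABA).
#'
#' @param n_per_group Named counts `c(control, relative, pwpp)`.
#' @param control_log10_mean Control-group mean log10 switch rate
#'   (log10 Hz; default -0.9, approx. 0.126 switches/s).
#' @param group_log10_rate_sd Common per-measurement SD of log10 rate.
#' @param target_d Standardized control-vs-PwPP difference (Cohen's d) on
#'   log10 rates; default 0.58, a medium effect.
#' @param relative_position Fraction placing the relatives' mean between the
#'   control and PwPP means (default 0.5).
#' @param symptom_rho Target Spearman correlation between switch rate and the
#'   BPRS disorganization score (default 0.264).
#' @param gaba_rho Target Spearman correlation between switch rate and GABA
#'   concentration (default -0.16).
#' @param retest_icc Target session-1/session-2 ICC(3,k) (default 0.88).
#' @param retest_fraction Fraction of each group returning for session 2.
#' @param block_log10_slope Per-block drift of log10 rate across the five
#'   bi-stable blocks (default 0; negative values emulate the practice /
#'   adaptation slowing seen across blocks).
#' @param n_bistable_blocks Bi-stable blocks per session (default 5).
#' @param miss_prob_kappa Beta concentration for between-subject spread of
#'   the real-switch lapse probability (`Inf` = identical across subjects).
#' @param benzodiazepine_prob Per-group probability of a benzodiazepine flag
#'   (named like `n_per_group`).
#' @param observer Baseline [observer_params()].
#' @param covariates Data frame of covariate targets (columns `covariate`,
#'   `rho`, `mean`, `sd`, `kind`); see `cylsfm:::.default_covariates()`.
#' @param seed Master seed; every random stream derives from it.
#'
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_per_group = c(control = 10, relative = 10, pwpp = 10))
#' @export
cohort_spec <- function(n_per_group = c(control = 40, relative = 43, pwpp = 65),
                        control_log10_mean = -0.9,
                        group_log10_rate_sd = 0.25,
                        target_d = 0.58,
                        relative_position = 0.5,
                        symptom_rho = 0.264,
                        gaba_rho = -0.16,
                        retest_icc = 0.88,
                        retest_fraction = 1,
                        block_log10_slope = 0,
                        n_bistable_blocks = 5,
                        miss_prob_kappa = 6,
                        benzodiazepine_prob = c(control = 0, relative = 0.07,
                                                pwpp = 0.26),
                        observer = observer_params(),
                        covariates = .default_covariates(),
                        seed = 1L) {
  groups <- c("control", "relative", "pwpp")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (!all(groups %in% names(n_per_group))) {
    abort("`n_per_group` must be named with control, relative and pwpp.")
  }
  n_per_group <- vapply(n_per_group[groups], as.integer, integer(1))
  if (any(n_per_group < 0)) abort("group sizes must be non-negative.")
  .assert_scalar_num(group_log10_rate_sd, "group_log10_rate_sd",
                     lower = 0, strict_lower = TRUE)
  .assert_scalar_num(retest_icc, "retest_icc", lower = 0, upper = 1 - 1e-12)
  .assert_scalar_num(retest_fraction, "retest_fraction", lower = 0, upper = 1)
  .assert_scalar_num(relative_position, "relative_position")
  stopifnot(inherits(observer, "observer_params"))

  covariates <- tibble::as_tibble(covariates)
  covariates$rho[covariates$covariate == "BPRS_D"] <- symptom_rho
  covariates$rho[covariates$covariate == "GABA"] <- gaba_rho
  bad <- covariates$covariate[abs(covariates$rho) >= 1]
  if (length(bad)) {
    abort(sprintf(
      "infeasible rank-correlation target for %s: |rho| must be < 1 (rate, %s)",
      bad[1], bad[1]
    ))
  }

  structure(
    list(
      n_per_group = n_per_group,
      control_log10_mean = control_log10_mean,
      group_log10_rate_sd = group_log10_rate_sd,
      target_d = target_d,
      relative_position = relative_position,
      retest_icc = retest_icc,
      retest_fraction = retest_fraction,
      block_log10_slope = block_log10_slope,
      n_bistable_blocks = as.integer(n_bistable_blocks),
      miss_prob_kappa = miss_prob_kappa,
      benzodiazepine_prob = benzodiazepine_prob[groups],
      observer = observer,
      covariates = covariates,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  n = %d control / %d relative / %d PwPP, seed %d\n",
              x$n_per_group[["control"]], x$n_per_group[["relative"]],
              x$n_per_group[["pwpp"]], x$seed))
  cat(sprintf("  log10 rate: control mean %.3g, sd %.3g, d = %.3g, ICC(3,k) = %.3g\n",
              x$control_log10_mean, x$group_log10_rate_sd, x$target_d,
              x$retest_icc))
  invisible(x)
}

# group means on the log10-rate scale implied by a cohort_spec
.group_means <- function(spec) {
  mu_c <- spec$control_log10_mean
  mu_p <- mu_c + spec$target_d * spec$group_log10_rate_sd
  mu_r <- mu_c + spec$relative_position * (mu_p - mu_c)
  c(control = mu_c, relative = mu_r, pwpp = mu_p)
}

# split total per-measurement variance into subject and session components so
# that ICC(3,k) over k sessions equals the target:
#   ICC(3,k) = k * vb / (k * vb + ve)
.icc_variances <- function(sd_total, icc, k = 2) {
  vt <- sd_total^2
  if (icc <= 0) return(c(vb = 0, ve = vt))
  ratio <- k * (1 - icc) / icc  # ve / vb
  vb <- vt / (1 + ratio)
  c(vb = vb, ve = vt - vb)
}
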
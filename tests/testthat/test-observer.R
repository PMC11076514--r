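test_that("bi-stable blocks are deterministic and truncate correctly", {
  obs <- observer_params()
  a <- simulate_bistable_block(obs, seed = 5)
  b <- simulate_bistable_block(obs, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_bistable_block(obs, seed = 6)))
  expect_true(all(a$t >= 0 & a$t < 120))
  expect_true(is.unsorted(a$t) == FALSE)
  # reported directions strictly alternate (renewal switches)
  expect_true(all(a$key[-1] != a$key[-nrow(a)]))
  # an onset latency beyond the block yields a legal empty stream
  slow <- observer_params(initial_latency_mean = 1e6)
  expect_equal(nrow(simulate_bistable_block(slow, seed = 1)), 0)
})

test_that("reported switch counts follow the gamma renewal mean", {
  # mean dominance duration = shape * scale = 5 s over a 120 s block
  obs <- observer_params(gamma_shape = 2, gamma_scale = 2.5,
                         initial_latency_mean = 1.5)
  counts <- vapply(1:1000, function(s) {
    nrow(simulate_bistable_block(obs, seed = s)) - 1L
  }, integer(1))
  expected <- (120 - obs$initial_latency_mean) / 5
  expect_lt(abs(mean(counts) - expected) / expected, 0.05)
})

test_that("long-run dominance durations match the generative gamma", {
  obs <- observer_params(gamma_shape = 4, gamma_scale = 2)
  dur <- unlist(lapply(1:5, function(s) {
    ev <- simulate_bistable_block(obs, duration = 1200, seed = 100 + s)
    extract_percepts(ev, 1200)$duration[
      !extract_percepts(ev, 1200)$censored]
  }))
  mu <- obs$gamma_shape * obs$gamma_scale
  sem <- sd(dur) / sqrt(length(dur))
  expect_lt(abs(mean(dur) - mu), 3 * sem + 1e-9)
})

test_that("duration CV is 1 for exponential renewals and falls with shape", {
  cvs <- vapply(c(1, 2, 4, 8), function(sh) {
    obs <- observer_params(gamma_shape = sh, gamma_scale = 5 / sh)
    dur <- unlist(lapply(1:4, function(s) {
      ev <- simulate_bistable_block(obs, duration = 1200, seed = 40 + s)
      p <- extract_percepts(ev, 1200)
      p$duration[!p$censored]
    }))
    sd(dur) / mean(dur)
  }, numeric(1))
  n <- 4 * 1200 / 5
  expect_lt(abs(cvs[1] - 1), 3 * sqrt(3 / (2 * n)))  # exponential: CV -> 1
  expect_true(all(diff(cvs) < 0))                    # monotone in shape
})

test_that("real-switch blocks implement the response model", {
  sched <- real_switch_schedule(seed = "paper")
  ideal <- observer_params(miss_prob = 0, error_prob = 0,
                           spontaneous_rate = 0, rt_mu = log(1),
                           rt_sigma = 0.05)
  ev <- simulate_real_switch_block(ideal, sched, seed = 8)
  sc <- score_real_switch(ev, sched)
  expect_equal(sc$n_correct, 11)
  expect_equal(sc$accuracy, 1)
  expect_true(sc$included)

  # total misses leave only the onset report
  deaf <- observer_params(miss_prob = 1, spontaneous_rate = 0)
  expect_equal(nrow(simulate_real_switch_block(deaf, sched, seed = 2)), 1)

  expect_identical(simulate_real_switch_block(ideal, sched, seed = 3),
                   simulate_real_switch_block(ideal, sched, seed = 3))
})

test_that("scored accuracy matches the closed-form response model", {
  sched <- real_switch_schedule(seed = "paper")
  obs <- observer_params(miss_prob = 0.2, error_prob = 0.05,
                         spontaneous_rate = 0, rt_mu = 0, rt_sigma = 0.4)
  acc <- vapply(1:500, function(s) {
    score_real_switch(simulate_real_switch_block(obs, sched, seed = s),
                      sched)$accuracy
  }, numeric(1))
  p_rt <- stats::plnorm(4, 0, 0.4)
  expected <- (1 - obs$miss_prob) * (1 - obs$error_prob) * p_rt
  se <- sqrt(expected * (1 - expected) / (11 * 500))
  expect_lt(abs(mean(acc) - expected), 4 * se + 0.005)
})

test_that("cohorts are reproducible and match their specification", {
  spec <- cohort_spec(n_per_group = c(control = 5, relative = 4, pwpp = 6),
                      seed = 31)
  coh <- simulate_cohort(spec)
  expect_identical(coh$sessions, simulate_cohort(spec)$sessions)
  expect_identical(coh$events, simulate_cohort(spec)$events)
  s1 <- coh$sessions[coh$sessions$session == 1, ]
  expect_equal(unname(table(s1$group)), c(5L, 4L, 6L), ignore_attr = TRUE)
  # 5 bi-stable blocks + 1 real-switch block per session
  blk <- dplyr::distinct(coh$events, subject_id, session, block, block_type)
  per <- dplyr::count(blk, subject_id, session, block_type)
  expect_true(all(per$n[per$block_type == "bistable"] == 5))
  expect_true(all(per$n[per$block_type == "real_switch"] == 1))
  expect_true(all(coh$events$t >= 0 & coh$events$t <= 120))
})

test_that("the count-level path reproduces the event path exactly", {
  spec <- cohort_spec(n_per_group = c(control = 6, relative = 6, pwpp = 6),
                      seed = 77)
  full <- simulate_cohort(spec, events = TRUE)
  fast <- simulate_cohort(spec, events = FALSE)
  expect_identical(full$bistable_counts, fast$bistable_counts)
  expect_identical(bistable_rate_metrics(full), bistable_rate_metrics(fast))
  # and scoring the events gives the same bi-stable rates as the counts
  sc <- score_cohort(full)
  scored <- dplyr::arrange(sc$subjects, subject_id, session)
  counted <- dplyr::arrange(bistable_rate_metrics(fast), subject_id, session)
  expect_equal(scored$mean_log10_rate, counted$mean_log10_rate)
})

test_that("a null specification yields no group effect and copulas hit their targets", {
  spec <- cohort_spec(n_per_group = c(control = 200, relative = 2, pwpp = 200),
                      target_d = 0, retest_fraction = 0, seed = 404)
  m <- bistable_rate_metrics(simulate_cohort(spec, events = FALSE))
  d <- cohens_d(m$mean_log10_rate[m$group == "pwpp"],
                m$mean_log10_rate[m$group == "control"])
  expect_lt(abs(d), 0.25)

  # rank-correlation targets recovered at n = 2000
  spec2 <- cohort_spec(n_per_group = c(control = 667, relative = 667,
                                       pwpp = 666),
                       retest_fraction = 0, seed = 505)
  coh2 <- simulate_cohort(spec2, events = FALSE)
  m2 <- bistable_rate_metrics(coh2)
  s1 <- dplyr::left_join(
    m2[m2$session == 1, ],
    coh2$sessions[coh2$sessions$session == 1,
                  c("subject_id", "BPRS_D", "GABA", "BACS")],
    by = "subject_id"
  )
  expect_lt(abs(spearman_test(s1, mean_log10_rate, BPRS_D)$estimate - 0.264),
            0.05)
  expect_lt(abs(spearman_test(s1, mean_log10_rate, GABA)$estimate - (-0.16)),
            0.05)
  expect_lt(abs(spearman_test(s1, mean_log10_rate, BACS)$estimate - (-0.139)),
            0.05)
})

test_that("near-perfect retest reliability collapses session differences", {
  spec <- cohort_spec(n_per_group = c(control = 30, relative = 2, pwpp = 30),
                      retest_icc = 0.999, seed = 12)
  coh <- simulate_cohort(spec, events = FALSE)
  w <- tidyr::pivot_wider(bistable_rate_metrics(coh)[, c("subject_id",
                                                         "session",
                                                         "mean_log10_rate")],
                          names_from = "session",
                          values_from = "mean_log10_rate")
  expect_gt(stats::cor(w$`1`, w$`2`), 0.9)
})

test_that("infeasible correlation targets are rejected by name", {
  expect_error(cohort_spec(symptom_rho = 1.2), "BPRS_D")
  expect_error(cohort_spec(gaba_rho = -1), "GABA")
})
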
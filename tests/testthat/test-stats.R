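test_that("Kruskal-Wallis matches the tie-corrected rank formula", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                  g = rep(c("a", "b", "c"), each = 3))
  k <- kw_test(d, y, g)
  expect_equal(k$statistic, oracle_kw_H(d$y, d$g))
  expect_equal(k$df, 2)

  # identical distributions across groups: H = 0, p = 1
  d0 <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  k0 <- kw_test(d0, y, g)
  expect_equal(k0$statistic, 0, tolerance = 1e-12)
  expect_equal(k0$p_value, 1)

  # with ties the correction still matches the oracle
  set.seed(1)
  dt <- data.frame(y = sample(1:4, 30, replace = TRUE),
                   g = rep(c("a", "b", "c"), 10))
  expect_equal(kw_test(dt, y, g)$statistic, oracle_kw_H(dt$y, dt$g))

  expect_error(kw_test(data.frame(y = 1:3, g = c("a", "a", "b")), y, g),
               "at least 2")
})

test_that("two-group Kruskal-Wallis equals the squared rank-sum z", {
  set.seed(7)
  for (i in 1:20) {
    a <- round(rnorm(8 + i %% 5), 1)
    b <- round(rnorm(10, 0.5), 1)
    d <- data.frame(y = c(a, b),
                    g = rep(c("a", "b"), c(length(a), length(b))))
    expect_equal(kw_test(d, y, g)$statistic,
                 oracle_ranksum_z(a, b)^2, tolerance = 1e-10)
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(3)
  d <- data.frame(y = rexp(30), g = rep(c("a", "b", "c"), 10))
  d2 <- dplyr::mutate(d, y = log(y + 1) * 10)
  expect_equal(kw_test(d, y, g)$statistic, kw_test(d2, y, g)$statistic)
  expect_equal(pairwise_kw(d, y, g)$statistic,
               pairwise_kw(d2, y, g)$statistic)
  s <- data.frame(x = rexp(20), yv = rexp(20))
  expect_equal(spearman_test(s, x, yv)$estimate,
               spearman_test(dplyr::mutate(s, x = exp(x)), x, yv)$estimate)
})

test_that("post-hoc pairwise comparisons behave as two-group tests", {
  d <- data.frame(y = c(1:10, 11:20, 1:10),
                  g = rep(c("a", "b", "c"), each = 10))
  pw <- pairwise_kw(d, y, g)
  expect_equal(nrow(pw), 3)
  ab <- pw[pw$group_a == "a" & pw$group_b == "b", ]
  expect_equal(ab$statistic, oracle_ranksum_z(1:10, 11:20)^2,
               tolerance = 1e-10)
  ac <- pw[pw$group_a == "a" & pw$group_b == "c", ]
  expect_equal(ac$statistic, 0, tolerance = 1e-12)
  expect_true(all(pw$p_bonferroni >= pw$p_value))
  expect_true(all(pw$p_bonferroni <= 1))
  expect_equal(pw$p_bonferroni, pmin(1, pw$p_value * 3))
})

test_that("KS D matches the exhaustive ECDF scan", {
  set.seed(11)
  a <- rgamma(50, 3, 1)
  b <- rgamma(50, 2, 0.7)
  ks <- ks_test_pooled(a, b)
  expect_equal(ks$statistic, oracle_ks_D(a, b))
  expect_equal(ks_test_pooled(a, a)$statistic, 0)
  expect_equal(ks_test_pooled(runif(20), runif(20) + 2)$statistic, 1)
  expect_error(ks_test_pooled(numeric(0), a), "nonempty")
})

test_that("Spearman correlation is tie-aware with sign conventions", {
  d <- data.frame(x = 1:20, y = (1:20)^3)
  expect_equal(spearman_test(d, x, y)$estimate, 1)
  d$y <- rev(d$y)
  expect_equal(spearman_test(d, x, y)$estimate, -1)
  # with ties: equals Pearson on average ranks
  dt <- data.frame(x = c(1, 2, 2, 3, 4, 4, 5, 6),
                   y = c(2, 1, 3, 3, 5, 4, 7, 6))
  expect_equal(spearman_test(dt, x, y)$estimate,
               stats::cor(rank(dt$x), rank(dt$y)))
  expect_warning(out <- spearman_test(data.frame(x = rep(1, 5), y = 1:5),
                                      x, y),
                 "constant")
  expect_true(is.na(out$estimate))
})

test_that("ICC(3,k) matches the ANOVA decomposition and its limits", {
  set.seed(5)
  y <- rnorm(12)
  dup <- data.frame(id = rep(1:12, 2), sess = rep(1:2, each = 12),
                    y = c(y, y))
  expect_equal(icc3k(dup, id, sess, y)$icc, 1)

  m <- matrix(rnorm(40), 20, 2)
  d <- data.frame(id = rep(1:20, 2), sess = rep(1:2, each = 20),
                  y = as.vector(m))
  expect_equal(icc3k(d, id, sess, y)$icc, oracle_icc3k_aov(m))

  # independent noise: ICC near 0 at large n
  mn <- matrix(rnorm(2000), 1000, 2)
  dn <- data.frame(id = rep(1:1000, 2), sess = rep(1:2, each = 1000),
                   y = as.vector(mn))
  expect_lt(abs(icc3k(dn, id, sess, y)$icc), 0.1)

  # reliability decreases monotonically as session noise grows
  base <- rnorm(200)
  iccs <- vapply(c(0.1, 0.5, 1, 2), function(s) {
    set.seed(42)
    m2 <- cbind(base + rnorm(200, 0, s), base + rnorm(200, 0, s))
    d2 <- data.frame(id = rep(1:200, 2), sess = rep(1:2, each = 200),
                     y = as.vector(m2))
    icc3k(d2, id, sess, y)$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))

  # incomplete rows are dropped with a message
  inc <- data.frame(id = c(1, 1, 2, 2, 3), sess = c(1, 2, 1, 2, 1),
                    y = rnorm(5))
  expect_message(ic <- icc3k(inc, id, sess, y), "dropping 1")
  expect_equal(ic$n, 2)
})

test_that("Cohen's d follows the pooled-SD formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3)), 2)
  set.seed(2)
  a <- rnorm(50, 1, 1); b <- rnorm(40, 0, 1)
  sp <- sqrt(((49) * var(a) + (39) * var(b)) / 88)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_warning(dd <- cohens_d(rep(1, 3), rep(1, 4)), "pooled SD")
  expect_true(is.na(dd))
})

test_that("the exclusion contingency test is Pearson chi-square with df 2", {
  prop <- rbind(included = c(10, 20, 30), excluded = c(1, 2, 3))
  expect_equal(exclusion_contingency(prop)$statistic, 0, tolerance = 1e-12)
  flat <- rbind(c(10, 10, 10), c(10, 10, 10))
  expect_equal(exclusion_contingency(flat)$statistic, 0)
  # counts as in a 3-group inclusion screen
  tab <- rbind(included = c(37, 37, 48), excluded = c(6, 7, 17))
  e <- exclusion_contingency(tab)
  expect_equal(e$statistic, oracle_chisq(tab))
  expect_equal(e$df, 2)
  expect_error(exclusion_contingency(rbind(c(0, 0, 0), c(1, 2, 3))),
               "marginal")
  expect_error(exclusion_contingency(rbind(c(1.5, 2, 3), c(1, 2, 3))),
               "integer")
})

test_that("the block effect detects drift and keeps its type-I rate", {
  # injected linear decline across blocks is detected
  set.seed(9)
  n <- 100
  d <- expand.grid(id = 1:n, block = 1:5)
  d$y <- rnorm(nrow(d)) - 0.3 * d$block + rnorm(n)[d$id]
  be <- block_effect(d, id, block, y)
  expect_lt(be$p_value, 0.001)
  expect_equal(be$df1, 4)
  expect_equal(be$df2, 4 * (n - 1))

  # null simulation: rejection close to the nominal 5%
  set.seed(10)
  rej <- vapply(1:1000, function(i) {
    dd <- expand.grid(id = 1:20, block = 1:5)
    dd$y <- rnorm(nrow(dd)) + rnorm(20)[dd$id]
    block_effect(dd, id, block, y)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)

  # Greenhouse-Geisser shrinks the degrees of freedom
  gg <- block_effect(d, id, block, y, gg = TRUE)
  expect_lte(gg$epsilon, 1)
  expect_lte(gg$df1, be$df1)
})

test_that("duration histograms normalize within group", {
  one <- data.frame(dur = runif(10, 0, 2), g = "a")
  h1 <- duration_histogram(one, dur, g, bin_edges = c(0, 2))
  expect_equal(h1$proportion, 1)

  h2 <- duration_histogram(data.frame(dur = c(1, 1, 3), g = "a"), dur, g,
                           bin_edges = c(0, 2, 4))
  expect_equal(h2$proportion, c(2 / 3, 1 / 3))

  set.seed(4)
  u <- data.frame(dur = runif(4000, 0, 4), g = rep(c("a", "b"), 2000))
  hu <- duration_histogram(u, dur, g, bin_edges = c(0, 2, 4))
  expect_equal(hu$proportion, rep(0.5, 4), tolerance = 0.05)
  agg <- tapply(hu$proportion, hu$group, sum)
  expect_equal(as.numeric(agg), c(1, 1), tolerance = 1e-12)

  expect_message(duration_histogram(data.frame(dur = c(1, 99), g = "a"),
                                    dur, g, bin_edges = c(0, 2, 4)),
                 "clipped")
})

test_that("metabolite correlations report pooled and per-group families", {
  set.seed(20)
  n <- 2000
  d <- data.frame(rate = rnorm(n), GABA = rnorm(n), glutamate = rnorm(n),
                  glutamine = rnorm(n),
                  group = sample(c("control", "pwpp"), n, TRUE))
  mc <- metabolite_correlations(d, rate, group = group)
  expect_equal(nrow(mc), 9)         # 3 metabolites x (pooled + 2 groups)
  pooled <- mc[mc$scope == "pooled", ]
  expect_true(all(abs(pooled$estimate) < 0.05))
  expect_true(all(mc$p_bonferroni >= mc$p_value - 1e-12))
  expect_true(all(mc$p_bonferroni <= 1))
  dconst <- d
  dconst$GABA <- 1
  expect_warning(mc2 <- metabolite_correlations(dconst, rate), "constant")
  expect_true(any(is.na(mc2$estimate[mc2$metabolite == "GABA"])))
})

test_that("run_stats assembles the full battery on a scored cohort", {
  # a lapse-prone observer so the inclusion screen actually excludes someone
  coh <- tiny_cohort(seed = 61, n = 10,
                     observer = observer_params(miss_prob = 0.4),
                     miss_prob_kappa = 2)
  sc <- score_cohort(coh)
  rep <- run_stats(sc, coh$sessions)
  expect_s3_class(rep, "sfm_stats_report")
  expect_true(all(c("kw_bistable_rate", "posthoc_bistable_rate",
                    "exclusion_contingency", "block_effect", "icc3k_retest",
                    "spearman_clinical", "spearman_metabolite") %in% rep$test))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1, na.rm = TRUE))
  expect_true(all(rep$p_bonferroni >= rep$p_value - 1e-12, na.rm = TRUE))
  expect_equal(sum(rep$test == "spearman_clinical"), 6)
  g <- glance(rep)
  expect_true(is.finite(g$icc_retest))
  expect_s3_class(tidy(sc), "tbl_df")
  expect_equal(nrow(glance(sc)), 1)
})
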
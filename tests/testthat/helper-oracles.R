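# Independent oracles used to cross-check the package's statistics and the
# real-switch scorer. All are deliberately naive, direct implementations.

make_events <- function(t, key) tibble::tibble(t = t, key = key)

# exhaustive-optimal bipartite matching between physical switches and
# responses (Kuhn's augmenting-path algorithm on the eligibility graph)
oracle_max_matching <- function(events, schedule, window) {
  st <- schedule$switch_times
  post <- schedule$directions[-1]
  elig <- lapply(seq_along(st), function(i) {
    lat <- events$t - st[i]
    which(events$key == post[i] & lat > 0 & lat < window)
  })
  match_resp <- rep(0L, nrow(events))
  visited <- rep(FALSE, nrow(events))
  try_augment <- function(i) {
    for (j in elig[[i]]) {
      if (!visited[j]) {
        visited[j] <<- TRUE
        if (match_resp[j] == 0L || try_augment(match_resp[j])) {
          match_resp[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_along(st)) {
    visited <- rep(FALSE, nrow(events))
    if (try_augment(i)) n <- n + 1L
  }
  n
}

# tie-corrected Kruskal-Wallis H by the rank formula
oracle_kw_H <- function(y, g) {
  g <- factor(g)
  n <- length(y)
  r <- rank(y)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# tie-corrected normal-approximation rank-sum z statistic
oracle_ranksum_z <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  ties <- table(c(a, b))
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  (w - e) / sqrt(v)
}

# Pearson chi-square by direct sum((O - E)^2 / E)
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# KS D by exhaustive scan of both ECDFs over the pooled support
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(fa - fb))
}

# ICC(3,k) through stats::aov mean squares (independent of the in-package
# sums-of-squares route)
oracle_icc3k_aov <- function(m) {
  d <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    sess = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(y ~ subj + sess, data = d))[[1]]
  bms <- tab["subj", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  (bms - ems) / bms
}

# small cohort used by several suites
tiny_cohort <- function(seed = 17, n = 4, ...) {
  simulate_cohort(cohort_spec(
    n_per_group = c(control = n, relative = n, pwpp = n), seed = seed, ...
  ))
}
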
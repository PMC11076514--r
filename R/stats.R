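# ---- elementary tests (tidy wrappers around the standard machinery) --------

.pull2 <- function(data, col) {
  data[[as_name(enquo(col))]] %||% abort("column not found in `data`.")
}

#' Kruskal-Wallis test on per-subject values
#'
#' Tie-corrected Kruskal-Wallis one-way nonparametric ANOVA across k groups;
#' the H statistic is chi-square distributed with k - 1 degrees of freedom.
#' With two groups this is the chi-square-distributed form of the
#' tie-corrected rank-sum test (H = z^2), which is how post-hoc pairwise
#' group comparisons are reported.
#'
#' @param data A data frame with one row per independent subject.
#' @param value,group Columns holding the response and the group label.
#' @return A one-row tibble: `test`, `statistic` (H), `df`, `p_value`, `n`,
#'   `n_groups`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' kw_test(d, y, g)
#' @export
kw_test <- function(data, value, group) {
  y <- .pull2(data, {{ value }})
  g <- factor(.pull2(data, {{ group }}))
  g <- droplevels(g)
  if (any(table(g) < 2)) abort("every group needs at least 2 observations.")
  k <- kruskal.test(y, g)
  tibble::tibble(
    test = "kruskal_wallis",
    statistic = unname(k$statistic),
    df = unname(k$parameter),
    p_value = k$p.value,
    n = length(y),
    n_groups = nlevels(g)
  )
}

#' Post-hoc pairwise two-group comparisons
#'
#' Runs the two-group (chi-square with 1 df) Kruskal-Wallis comparison for
#' every pair of groups, Bonferroni-corrects over the pairs, and attaches
#' Cohen's d for each pair.
#'
#' @inheritParams kw_test
#' @return A tibble with one row per pair: `group_a`, `group_b`, `statistic`,
#'   `df`, `p_value`, `p_bonferroni`, `cohens_d`, `n_a`, `n_b`.
#' @export
pairwise_kw <- function(data, value, group) {
  y <- .pull2(data, {{ value }})
  g <- droplevels(factor(.pull2(data, {{ group }})))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    sel <- g %in% pr
    k <- kruskal.test(y[sel], droplevels(g[sel]))
    tibble::tibble(
      group_a = pr[1], group_b = pr[2],
      statistic = unname(k$statistic), df = 1,
      p_value = k$p.value,
      cohens_d = cohens_d(y[g == pr[1]], y[g == pr[2]]),
      n_a = sum(g == pr[1]), n_b = sum(g == pr[2])
    )
  })
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  dplyr::relocate(out, "p_bonferroni", .after = "p_value")
}

#' Two-sample Kolmogorov-Smirnov test on pooled percept durations
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p value is asymptotic. Durations are pooled across participants
#' within each group, as for group-wise duration histograms; the number of
#' contributing subjects is reported alongside the pooled sample sizes.
#'
#' @param a,b Numeric samples (pooled durations for two groups).
#' @param n_subjects_a,n_subjects_b Optional contributing-subject counts,
#'   carried through as metadata.
#' @return A one-row tibble: `test`, `statistic` (D), `p_value`, `n_a`,
#'   `n_b`, `n_subjects_a`, `n_subjects_b`.
#' @export
ks_test_pooled <- function(a, b, n_subjects_a = NA_integer_,
                           n_subjects_b = NA_integer_) {
  if (!length(a) || !length(b)) abort("both samples must be nonempty.")
  k <- suppressWarnings(ks.test(a, b))
  tibble::tibble(
    test = "ks_two_sample",
    statistic = unname(k$statistic),
    p_value = k$p.value,
    n_a = length(a), n_b = length(b),
    n_subjects_a = n_subjects_a, n_subjects_b = n_subjects_b
  )
}

#' Spearman rank correlation
#'
#' Tie-aware (average-rank) Spearman correlation with the t-approximation p
#' value. Constant input yields an NA estimate with a warning rather than an
#' error.
#'
#' @param data A data frame (one row per independent subject; repeat
#'   sessions must be excluded upstream).
#' @param x,y Columns to correlate.
#' @return A one-row tibble: `test`, `estimate` (rho), `p_value`, `n`.
#' @export
spearman_test <- function(data, x, y) {
  xv <- .pull2(data, {{ x }})
  yv <- .pull2(data, {{ y }})
  cc <- complete.cases(xv, yv)
  xv <- xv[cc]; yv <- yv[cc]
  if (length(xv) < 4) abort("at least 4 complete pairs are required.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    warn("constant input: Spearman correlation undefined.")
    return(tibble::tibble(test = "spearman", estimate = NA_real_,
                          p_value = NA_real_, n = length(xv)))
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = FALSE))
  tibble::tibble(
    test = "spearman",
    estimate = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(xv)
  )
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled (n - 1 weighted) standard deviation. In this pipeline it is
#' computed on log10 switch rates, the analysis scale.
#'
#' @param a,b Numeric samples.
#' @return Cohen's d (NA with a warning when the pooled SD is zero).
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))   # -2
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("both samples need at least 2 observations.")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    warn("zero pooled SD: Cohen's d undefined.")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed, consistency, average-measures intraclass correlation:
#' `(BMS - EMS) / BMS` from the two-way (subject x session) ANOVA
#' decomposition, the standard index of test-retest reliability for the mean
#' of k repeated measurements per subject. Rows with missing sessions are
#' dropped (with a message).
#'
#' @param data Long data frame.
#' @param subject,session,value Columns naming the subject, the repeated
#'   session index, and the measurement.
#' @return A one-row tibble: `icc` (ICC(3,k)), `n` (complete subjects), `k`,
#'   `bms`, `ems`.
#' @examples
#' d <- data.frame(id = rep(1:6, 2), sess = rep(1:2, each = 6),
#'                 y = c(1:6, 1:6 + rnorm(6, 0, 0.1)))
#' icc3k(d, id, sess, y)
#' @export
icc3k <- function(data, subject, session, value) {
  s <- factor(.pull2(data, {{ subject }}))
  w <- factor(.pull2(data, {{ session }}))
  y <- .pull2(data, {{ value }})
  wide <- tapply(y, list(s, w), mean)
  ok <- complete.cases(wide)
  if (sum(!ok)) inform(sprintf("dropping %d subject(s) with incomplete sessions.",
                               sum(!ok)))
  m <- wide[ok, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("ICC(3,k) needs >= 2 complete subjects and >= 2 sessions.")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  jms <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  ems <- sse / ((n - 1) * (k - 1))
  tibble::tibble(icc = (bms - ems) / bms, n = n, k = k, bms = bms, ems = ems,
                 jms = jms)
}

#' Chi-square contingency test for exclusion rates by group
#'
#' Pearson chi-square (no continuity correction) on an included/excluded by
#' group contingency table, testing whether exclusion rates differ across
#' groups.
#'
#' @param tab A 2 x k matrix/table of counts, or a data frame with logical
#'   `included` and `group` columns to be tabulated.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`, `n`.
#' @examples
#' exclusion_contingency(rbind(included = c(37, 37, 48),
#'                             excluded = c(6, 7, 17)))
#' @export
exclusion_contingency <- function(tab) {
  if (is.data.frame(tab)) {
    tab <- table(factor(tab$included, levels = c(TRUE, FALSE)), tab$group)
  }
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has a zero marginal.")
  }
  ch <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(
    test = "exclusion_contingency",
    statistic = unname(ch$statistic),
    df = unname(ch$parameter),
    p_value = ch$p.value,
    n = sum(tab)
  )
}

#' Repeated-measures ANOVA for the block (time-on-task) effect
#'
#' One-way repeated-measures ANOVA with block number as the within-subject
#' factor, testing for drift of switch rates across the five bi-stable
#' blocks. Uses the standard subject-stratified error decomposition; the
#' Greenhouse-Geisser sphericity correction is available as an option.
#'
#' @param data Long data frame of per-block values.
#' @param subject,block,value Columns naming subject, block index, value.
#' @param gg Apply the Greenhouse-Geisser epsilon correction (default FALSE).
#' @return A one-row tibble: `test`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `epsilon`, `n`.
#' @export
block_effect <- function(data, subject, block, value, gg = FALSE) {
  s <- factor(.pull2(data, {{ subject }}))
  b <- factor(.pull2(data, {{ block }}))
  y <- .pull2(data, {{ value }})
  wide <- tapply(y, list(s, b), mean)
  ok <- complete.cases(wide)
  if (sum(!ok)) inform(sprintf("dropping %d subject(s) with missing blocks.",
                               sum(!ok)))
  keep <- rownames(wide)[ok]
  sel <- s %in% keep
  d <- data.frame(s = droplevels(s[sel]), b = b[sel], y = y[sel])
  fit <- aov(y ~ b + Error(s), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  fstat <- tab["b", "F value"]
  df1 <- tab["b", "Df"]
  df2 <- tab["Residuals", "Df"]
  eps <- 1
  if (gg) {
    m <- wide[ok, , drop = FALSE]
    S <- stats::cov(m)
    k <- ncol(S)
    # Greenhouse-Geisser epsilon from the doubly centred covariance matrix
    C <- diag(k) - 1 / k
    Sc <- C %*% S %*% C
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    eps <- min(1, max(eps, 1 / (k - 1)))
  }
  tibble::tibble(
    test = "block_effect_rm_anova",
    statistic = fstat,
    df1 = df1 * eps, df2 = df2 * eps,
    p_value = pf(fstat, df1 * eps, df2 * eps, lower.tail = FALSE),
    epsilon = eps,
    n = sum(ok)
  )
}

#' Normalized percept-duration histogram by group
#'
#' Bins pooled percept durations and normalizes each group's counts by that
#' group's total number of responses, so per-group histograms sum to 1.
#' Durations beyond the final bin edge are clipped into the final bin (with
#' a message).
#'
#' @param data Long data frame of durations.
#' @param value,group Columns holding durations and group labels.
#' @param bin_edges Increasing numeric vector of bin edges (seconds).
#' @return A tibble: `group`, `bin_lo`, `bin_hi`, `count`, `proportion`.
#' @export
duration_histogram <- function(data, value, group,
                               bin_edges = seq(0, 60, by = 2)) {
  y <- .pull2(data, {{ value }})
  g <- droplevels(factor(.pull2(data, {{ group }})))
  if (!length(y)) abort("no durations supplied.")
  over <- sum(y >= max(bin_edges))
  if (over) inform(sprintf("%d duration(s) beyond the final bin edge clipped into the final bin.",
                           over))
  y <- pmin(y, max(bin_edges) - 1e-9)
  y <- pmax(y, min(bin_edges))
  bins <- cut(y, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  tab <- table(g, bins)
  tot <- rowSums(tab)
  nb <- length(bin_edges) - 1
  tibble::tibble(
    group = rep(rownames(tab), each = nb),
    bin_lo = rep(bin_edges[-length(bin_edges)], times = nrow(tab)),
    bin_hi = rep(bin_edges[-1], times = nrow(tab)),
    count = as.vector(t(tab)),
    proportion = as.vector(t(tab / tot))
  )
}

#' Spearman correlations between metabolite concentrations and switch rates
#'
#' Correlates each metabolite (occipital GABA, glutamate, glutamine
#' concentrations from MRS) with per-subject switch rates, pooled across
#' groups and within each group, Bonferroni-correcting within the pooled
#' family and within the per-group family for each metabolite. Repeat
#' sessions must be excluded upstream.
#'
#' @param data One row per subject: a rate column plus metabolite columns.
#' @param rate Column of per-subject (session-1) switch rates.
#' @param metabolites Character vector of metabolite column names.
#' @param group Optional column of group labels for per-group correlations.
#' @return A tibble with one row per (metabolite, scope): `metabolite`,
#'   `scope`, `estimate`, `p_value`, `p_bonferroni`, `n`.
#' @export
metabolite_correlations <- function(data, rate,
                                    metabolites = c("GABA", "glutamate",
                                                    "glutamine"),
                                    group = NULL) {
  rate_v <- .pull2(data, {{ rate }})
  gq <- enquo(group)
  gv <- if (!rlang::quo_is_null(gq)) droplevels(factor(.pull2(data, !!gq)))
  scopes <- c("pooled", if (!is.null(gv)) levels(gv))
  out <- purrr::map_dfr(metabolites, function(m) {
    if (!m %in% names(data)) abort(sprintf("metabolite column `%s` not found.", m))
    purrr::map_dfr(scopes, function(sc) {
      sel <- if (sc == "pooled") rep(TRUE, length(rate_v)) else gv == sc
      d <- data.frame(r = rate_v[sel], m = data[[m]][sel])
      st <- tryCatch(spearman_test(d, r, m), error = function(e) {
        inform(sprintf("%s (%s): %s", m, sc, conditionMessage(e)))
        tibble::tibble(estimate = NA_real_, p_value = NA_real_, n = nrow(d))
      })
      tibble::tibble(metabolite = m, scope = sc,
                     estimate = st$estimate, p_value = st$p_value, n = st$n)
    })
  })
  out |>
    dplyr::group_by(.data$scope == "pooled") |>
    dplyr::mutate(p_bonferroni = pmin(1, .data$p_value * dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::select("metabolite", "scope", "estimate", "p_value",
                  "p_bonferroni", "n")
}
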
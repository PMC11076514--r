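#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for cylsfm result objects
#'
#' `tidy()` returns the per-row result table of an object; `glance()` returns
#' a one-row summary.
#'
#' @param x An `sfm_scores` or `sfm_stats_report` object.
#' @param ... Unused.
#' @name sfm_tidiers
NULL

#' Run the group-level statistical battery over a scored cohort
#'
#' Reproduces the full statistical analysis of the paradigm on included
#' session-1 data: Kruskal-Wallis group tests on mean log10 switch rates for
#' the bi-stable and real-switch tasks, post-hoc pairwise two-group
#' comparisons with Bonferroni correction and Cohen's d, two-sample
#' Kolmogorov-Smirnov tests on pooled percept-duration distributions per
#' task, the exclusion-rate contingency test, the repeated-measures block
#' (time-on-task) effect, Kruskal-Wallis tests on the coefficient of
#' variation of percept durations, test-retest ICC(3,k) over repeat
#' sessions, Spearman correlations between clinical scores and switch rates
#' (Bonferroni over the clinical family), and Spearman correlations between
#' metabolite concentrations and switch rates (pooled and per group).
#'
#' @param scores An [score_cohort()] result.
#' @param sessions The cohort's `sessions` tibble (group labels, covariates).
#' @param clinical Character vector of clinical covariate columns present in
#'   `sessions` to correlate with switch rate.
#' @param metabolites Character vector of metabolite columns.
#' @param gg Greenhouse-Geisser correction for the block effect.
#' @return An `sfm_stats_report`: a tibble with columns `test`, `term`,
#'   `statistic`, `df1`, `df2`, `estimate`, `p_value`, `p_bonferroni`, `n`.
#' @examples
#' spec <- cohort_spec(n_per_group = c(control = 6, relative = 6, pwpp = 6),
#'                     seed = 2)
#' coh <- simulate_cohort(spec)
#' rep <- run_stats(score_cohort(coh), coh$sessions)
#' dplyr::filter(rep, test == "kw_bistable_rate")
#' @export
run_stats <- function(scores, sessions,
                      clinical = c("BPRS", "SPQ", "BACS", "SGI", "BPRS_D",
                                   "SPQ_CP"),
                      metabolites = c("GABA", "glutamate", "glutamine"),
                      gg = FALSE) {
  stopifnot(inherits(scores, "sfm_scores"))
  subj <- dplyr::left_join(
    scores$subjects,
    dplyr::distinct(sessions, .data$subject_id, .data$group),
    by = "subject_id"
  )
  s1 <- dplyr::filter(subj, .data$session == 1, .data$included)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- tibble::tibble(...)
  safely_add <- function(expr) {
    tryCatch(expr, error = function(e) {
      warn(sprintf("skipping a report entry: %s", conditionMessage(e)))
      NULL
    })
  }

  ## group differences in switch rate --------------------------------------
  safely_add({
    k <- kw_test(s1, mean_log10_rate, group)
    add(test = "kw_bistable_rate", term = "group",
        statistic = k$statistic, df1 = k$df, df2 = NA_real_,
        estimate = NA_real_, p_value = k$p_value, p_bonferroni = NA_real_,
        n = k$n)
  })
  rs_rates <- scores$blocks |>
    dplyr::filter(.data$block_type == "real_switch", .data$session == 1) |>
    dplyr::semi_join(s1, by = c("subject_id", "session")) |>
    dplyr::left_join(dplyr::distinct(sessions, .data$subject_id, .data$group),
                     by = "subject_id")
  safely_add({
    k <- kw_test(rs_rates, log10_rate, group)
    add(test = "kw_realswitch_rate", term = "group",
        statistic = k$statistic, df1 = k$df, df2 = NA_real_,
        estimate = NA_real_, p_value = k$p_value, p_bonferroni = NA_real_,
        n = k$n)
  })
  safely_add({
    pw <- pairwise_kw(s1, mean_log10_rate, group)
    for (i in seq_len(nrow(pw))) {
      add(test = "posthoc_bistable_rate",
          term = paste(pw$group_a[i], "vs", pw$group_b[i]),
          statistic = pw$statistic[i], df1 = pw$df[i], df2 = NA_real_,
          estimate = pw$cohens_d[i], p_value = pw$p_value[i],
          p_bonferroni = pw$p_bonferroni[i], n = pw$n_a[i] + pw$n_b[i])
    }
  })

  ## percept-duration distributions (pooled within group) -------------------
  dur1 <- scores$durations |>
    dplyr::filter(.data$session == 1) |>
    dplyr::semi_join(s1, by = c("subject_id", "session")) |>
    dplyr::left_join(dplyr::distinct(sessions, .data$subject_id, .data$group),
                     by = "subject_id")
  for (bt in unique(dur1$block_type)) {
    db <- dur1[dur1$block_type == bt, ]
    lv <- levels(droplevels(factor(db$group)))
    for (pr in utils::combn(lv, 2, simplify = FALSE)) {
      safely_add({
        a <- db$duration[db$group == pr[1]]
        b <- db$duration[db$group == pr[2]]
        ks <- ks_test_pooled(
          a, b,
          n_subjects_a = dplyr::n_distinct(db$subject_id[db$group == pr[1]]),
          n_subjects_b = dplyr::n_distinct(db$subject_id[db$group == pr[2]])
        )
        add(test = paste0("ks_durations_", bt),
            term = paste(pr[1], "vs", pr[2]),
            statistic = ks$statistic, df1 = NA_real_, df2 = NA_real_,
            estimate = NA_real_, p_value = ks$p_value,
            p_bonferroni = NA_real_, n = ks$n_a + ks$n_b)
      })
    }
  }

  ## exclusion contingency ---------------------------------------------------
  safely_add({
    ex <- subj |>
      dplyr::filter(.data$session == 1) |>
      dplyr::count(.data$group, .data$included) |>
      tidyr::complete(.data$group, included = c(TRUE, FALSE),
                      fill = list(n = 0))
    tab <- matrix(ex$n[order(ex$group, !ex$included)], nrow = 2)
    e <- exclusion_contingency(tab)
    add(test = "exclusion_contingency", term = "included x group",
        statistic = e$statistic, df1 = e$df, df2 = NA_real_,
        estimate = NA_real_, p_value = e$p_value, p_bonferroni = NA_real_,
        n = e$n)
  })

  ## block (time-on-task) effect --------------------------------------------
  safely_add({
    bl <- scores$blocks |>
      dplyr::filter(.data$block_type == "bistable", .data$session == 1) |>
      dplyr::semi_join(s1, by = c("subject_id", "session"))
    be <- block_effect(bl, subject_id, block, log10_rate, gg = gg)
    add(test = "block_effect", term = "block",
        statistic = be$statistic, df1 = be$df1, df2 = be$df2,
        estimate = NA_real_, p_value = be$p_value, p_bonferroni = NA_real_,
        n = be$n)
  })

  ## percept-duration variability (CV) ---------------------------------------
  for (cvcol in c("bistable_cv", "real_switch_cv")) {
    if (!cvcol %in% names(s1)) next
    safely_add({
      d <- s1[!is.na(s1[[cvcol]]), ]
      k <- kw_test(d, !!rlang::sym(cvcol), group)
      add(test = paste0("kw_", cvcol), term = "group",
          statistic = k$statistic, df1 = k$df, df2 = NA_real_,
          estimate = NA_real_, p_value = k$p_value, p_bonferroni = NA_real_,
          n = k$n)
    })
  }

  ## test-retest reliability --------------------------------------------------
  safely_add({
    rt <- subj |>
      dplyr::filter(.data$included) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::filter(dplyr::n() == 2) |>
      dplyr::ungroup()
    ic <- icc3k(rt, subject_id, session, mean_log10_rate)
    add(test = "icc3k_retest", term = "session 1 vs 2",
        statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
        estimate = ic$icc, p_value = NA_real_, p_bonferroni = NA_real_,
        n = ic$n)
  })

  ## clinical symptom correlations -------------------------------------------
  clin <- intersect(clinical, names(sessions))
  s1c <- dplyr::left_join(
    s1, dplyr::filter(sessions, .data$session == 1),
    by = c("subject_id", "session", "group")
  )
  m_clin <- length(clin)
  for (cv in clin) {
    safely_add({
      st <- spearman_test(s1c, mean_log10_rate, !!rlang::sym(cv))
      add(test = "spearman_clinical", term = cv,
          statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
          estimate = st$estimate, p_value = st$p_value,
          p_bonferroni = pmin(1, st$p_value * m_clin), n = st$n)
    })
  }

  ## metabolite correlations ---------------------------------------------------
  met <- intersect(metabolites, names(sessions))
  if (length(met)) {
    safely_add({
      mc <- metabolite_correlations(s1c, mean_log10_rate, met, group = group)
      for (i in seq_len(nrow(mc))) {
        add(test = "spearman_metabolite",
            term = paste(mc$metabolite[i], mc$scope[i], sep = ":"),
            statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
            estimate = mc$estimate[i], p_value = mc$p_value[i],
            p_bonferroni = mc$p_bonferroni[i], n = mc$n[i])
      }
    })
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("sfm_stats_report", class(out))
  out
}

#' @rdname sfm_tidiers
#' @export
tidy.sfm_stats_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sfm_stats_report")
  out
}

#' @rdname sfm_tidiers
#' @export
glance.sfm_stats_report <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
    icc_retest = x$estimate[x$test == "icc3k_retest"][1],
    cohens_d_control_pwpp =
      x$estimate[x$test == "posthoc_bistable_rate" &
                   x$term == "control vs pwpp"][1]
  )
}

#' @export
print.sfm_stats_report <- function(x, ...) {
  cat("<sfm_stats_report> ", nrow(x), " entries\n", sep = "")
  NextMethod()
}
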
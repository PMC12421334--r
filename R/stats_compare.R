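#' Spearman correlation matrix
#'
#' Tie-corrected Spearman rank correlations and two-sided p-values over
#' pairwise-complete observations (within the already list-wise-filtered
#' sample). Cells with a constant variable or fewer than 3 complete pairs
#' are flagged `NA`.
#'
#' @param records Cohort data frame.
#' @param variables Variables to correlate (default: the registry
#'   variables present in `records`).
#' @param group `"all"`, `"women"` or `"men"`.
#' @return List with matrices `rho` and `p`.
#' @export
spearman_matrix <- function(records, variables = NULL,
                            group = c("all", "women", "men")) {
  group <- match.arg(group)
  if (group == "women") records <- records[records$sex == "woman", ]
  if (group == "men") records <- records[records$sex == "man", ]
  if (is.null(variables)) {
    variables <- intersect(analysis_variables(), names(records))
  }
  m <- length(variables)
  rho <- p <- matrix(NA_real_, m, m, dimnames = list(variables, variables))
  for (i in seq_len(m)) {
    for (j in i:m) {
      x <- records[[variables[i]]]
      y <- records[[variables[j]]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || length(unique(x[ok])) < 2 ||
          length(unique(y[ok])) < 2) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    rho[i, i] <- 1
    p[i, i] <- 0
  }
  list(rho = rho, p = p)
}

#' Compare a numeric variable between the sex groups
#'
#' The survey-style route: Student's t-test when both groups look Gaussian,
#' the Mann-Whitney test otherwise. The visual Q-Q check is
#' operationalized as Shapiro-Wilk at alpha = 0.05 in both groups
#' (`normality_rule = "shapiro"`); the rule can be forced for calibration
#' studies. Two-sided throughout.
#'
#' @param values_women,values_men Numeric vectors (NAs dropped).
#' @param normality_rule `"shapiro"`, `"always_normal"` (force t-test) or
#'   `"never_normal"` (force Mann-Whitney).
#' @param shapiro_alpha Normality-test level for the `"shapiro"` rule.
#' @return List of class `clbp_comparison`: `test_used`, `statistic`,
#'   `p_value`, `group_summaries`.
#' @export
compare_numeric <- function(values_women, values_men,
                            normality_rule = c("shapiro", "always_normal",
                                               "never_normal"),
                            shapiro_alpha = 0.05) {
  normality_rule <- match.arg(normality_rule)
  x <- values_women[!is.na(values_women)]
  y <- values_men[!is.na(values_men)]
  if (length(x) < 2 || length(y) < 2) {
    stop("compare_numeric(): both groups need at least 2 observations")
  }
  normal <- switch(normality_rule,
    always_normal = TRUE,
    never_normal = FALSE,
    shapiro = {
      sw <- function(v) {
        if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) {
          return(FALSE)
        }
        stats::shapiro.test(v)$p.value >= shapiro_alpha
      }
      sw(x) && sw(y)
    })
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(test_used = "student_t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    res <- list(test_used = "mann_whitney",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  res$group_summaries <- rbind(women = qs(x), men = qs(y))
  colnames(res$group_summaries) <- c("q1", "median", "q3")
  structure(res, class = "clbp_comparison")
}

#' Compare a nominal variable between groups
#'
#' Chi-squared test without continuity correction when all expected counts
#' are at least 5, Fisher's exact test otherwise; two-sided.
#'
#' @param table_counts An r x c matrix of non-negative integer counts.
#' @return A `clbp_comparison` with counts/percentages as summaries.
#' @export
compare_nominal <- function(table_counts) {
  tab <- as.matrix(table_counts)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("compare_nominal(): counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("compare_nominal(): degenerate table (zero margin)")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(tab, correct = FALSE)
    res <- list(test_used = "chi2", statistic = unname(ct$statistic),
                p_value = ct$p.value)
  } else {
    ft <- stats::fisher.test(tab)
    res <- list(test_used = "fisher_exact",
                statistic = NA_real_, p_value = ft$p.value)
  }
  res$group_summaries <- cbind(count = tab,
                               pct = 100 * prop.table(tab, 1))
  structure(res, class = "clbp_comparison")
}

#' Work-factor associations with pain interference
#'
#' For each binary work factor (the back-relevant repetitive gestures, the
#' absence of consecutive rest days, sick-leave history), compares pain
#' interference between exposed and unexposed subjects with a Mann-Whitney
#' test, overall or within one sex stratum. Factors with an empty level
#' are flagged and not tested.
#'
#' @param records Cohort data frame with gesture flags and
#'   `pain_interference`.
#' @param group `"all"`, `"women"` or `"men"`.
#' @param factors Optional character vector of logical column names to
#'   test; defaults to `gesture_<g>` for the back-relevant gestures plus
#'   `no_rest_days` (negation of `rest_days_consecutive`) and
#'   `sick_leave_history`.
#' @return Data frame: `factor`, `n_exposed`, `n_unexposed`,
#'   `median_exposed`, `median_unexposed`, `p_value`, `tested`.
#' @export
work_factor_associations <- function(records,
                                     group = c("all", "women", "men"),
                                     factors = NULL) {
  group <- match.arg(group)
  if (group == "women") records <- records[records$sex == "woman", ]
  if (group == "men") records <- records[records$sex == "man", ]
  records$no_rest_days <- !records$rest_days_consecutive
  if (is.null(factors)) {
    factors <- c(paste0("gesture_", gesture_names(back_relevant = TRUE)),
                 "no_rest_days", "sick_leave_history")
  }
  rows <- lapply(factors, function(f) {
    flag <- records[[f]]
    y <- records$pain_interference
    ok <- !is.na(flag) & !is.na(y)
    flag <- flag[ok]
    y <- y[ok]
    n1 <- sum(flag)
    n0 <- sum(!flag)
    if (n1 == 0 || n0 == 0) {
      return(data.frame(factor = f, n_exposed = n1, n_unexposed = n0,
                        median_exposed = NA_real_,
                        median_unexposed = NA_real_,
                        p_value = NA_real_, tested = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(y[flag], y[!flag],
                                              exact = FALSE))
    data.frame(factor = f, n_exposed = n1, n_unexposed = n0,
               median_exposed = stats::median(y[flag]),
               median_unexposed = stats::median(y[!flag]),
               p_value = wt$p.value, tested = TRUE)
  })
  do.call(rbind, rows)
}

#' Sex-group comparison table for the numeric analysis variables
#'
#' Table-II-style descriptive/comparative summary: per variable, the
#' sex-group quartiles, the test chosen by the normality rule and its
#' p-value. A Benjamini-Hochberg adjusted column can be added (off by
#' default, matching raw-p reporting).
#'
#' @param records Cohort data frame with both sexes.
#' @param variables Variables to compare (default: registry variables).
#' @param adjust Add a `p_adjusted` (BH) column.
#' @return Data frame, one row per variable.
#' @export
compare_sex_groups <- function(records, variables = NULL, adjust = FALSE) {
  if (is.null(variables)) {
    variables <- intersect(analysis_variables(), names(records))
  }
  rows <- lapply(variables, function(v) {
    cmp <- compare_numeric(records[[v]][records$sex == "woman"],
                           records[[v]][records$sex == "man"])
    s <- cmp$group_summaries
    data.frame(variable = v,
               women_median = s["women", "median"],
               women_q1 = s["women", "q1"], women_q3 = s["women", "q3"],
               men_median = s["men", "median"],
               men_q1 = s["men", "q1"], men_q3 = s["men", "q3"],
               test = cmp$test_used, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
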
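# Group-level comparisons: percent change, the monolayer diameter-to-count
# predictor, Welch's t-test, condition summaries and condition contrasts.

#' Percent change between two group means
#'
#' `100 * (test - reference) / reference`; negative values are reductions
#' (a "-13.1" is rendered "reduced by 13.1%").
#'
#' @param reference_mean,test_mean Group means; `reference_mean` must be
#'   non-zero.
#' @return Percent change (signed).
#' @export
#' @examples
#' percent_change(1222.5, 1062.3) # -13.1
percent_change <- function(reference_mean, test_mean) {
  if (!is.numeric(reference_mean) || length(reference_mean) != 1L ||
      !is.finite(reference_mean) || reference_mean == 0) {
    stop_ionopattern("undefined_change",
                     "reference mean must be finite and non-zero")
  }
  100 * (test_mean - reference_mean) / reference_mean
}

#' Predicted cell-number change of a monolayer under a diameter change
#'
#' For a two-dimensional single-cell layer whose linear cell size changes by
#' the fraction `delta_diameter` (at constant domain area), the number of
#' cells per unit area changes by `(1 + delta)^-2 - 1`. Returned in percent.
#'
#' @param delta_diameter Fractional diameter change (> -1); e.g. `-0.079`
#'   for a 7.9% smaller diameter.
#' @return Predicted percent change in cell number per unit area.
#' @export
#' @examples
#' predicted_density_change(-0.079) # +17.9%
predicted_density_change <- function(delta_diameter) {
  if (!is.numeric(delta_diameter) || length(delta_diameter) != 1L ||
      !is.finite(delta_diameter) || delta_diameter <= -1) {
    stop_ionopattern("invalid_input", "delta_diameter must be > -1")
  }
  100 * ((1 + delta_diameter)^-2 - 1)
}

#' Two-tailed Welch t-test (unequal variances)
#'
#' Computed from the defining formulas:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p from the t
#' distribution. When both sample variances are zero the test is flagged
#' degenerate (`t = 0, p = 1` for equal means; `|t| = Inf, p = 0`
#' otherwise).
#'
#' @param sample_a,sample_b Numeric vectors with at least 2 values each.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a)
  sample_b <- as.numeric(sample_b)
  n_a <- length(sample_a)
  n_b <- length(sample_b)
  if (n_a < 2L || n_b < 2L || anyNA(sample_a) || anyNA(sample_b)) {
    stop_ionopattern("insufficient_data",
                     "each sample needs >= 2 non-missing values")
  }
  m_a <- mean(sample_a); m_b <- mean(sample_b)
  v_a <- stats::var(sample_a); v_b <- stats::var(sample_b)
  se2 <- v_a / n_a + v_b / n_b
  if (se2 == 0) {
    eq <- isTRUE(all.equal(m_a, m_b))
    return(list(t = if (eq) 0 else sign(m_a - m_b) * Inf,
                df = NA_real_, p = if (eq) 1 else 0,
                mean_a = m_a, mean_b = m_b, degenerate = TRUE))
  }
  t_stat <- (m_a - m_b) / sqrt(se2)
  df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df),
       mean_a = m_a, mean_b = m_b, degenerate = FALSE)
}

#' Significance tier used in the figure legends
#'
#' @param p A p-value.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `"NS"` otherwise (`NA` propagates).
#' @export
significance_tier <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "NS"
  }, character(1))
}

# Numeric per-embryo statistics eligible for group summaries/contrasts.
summary_statistics <- function(summaries) {
  cols <- vapply(summaries, is.numeric, TRUE)
  setdiff(names(summaries)[cols], c("counting_area_um2"))
}

#' Per-condition mean and standard error of every statistic
#'
#' Summaries are computed per embryo first and then averaged across embryos
#' (never pooled across embryos), matching the mean +/- s.e.m. presentation
#' of the study. The SEM uses the n-1 sample standard deviation; for a
#' single embryo it is reported as `NA`. Embryos with an undefined value of
#' a statistic are dropped from that statistic's summary (`n_embryos`
#' reflects the values used).
#'
#' @param summaries Per-embryo summary table from [summarize_cohort()].
#' @param statistics Character vector of summary columns; default all
#'   numeric statistics.
#' @return Long data.frame: `condition, statistic, n_embryos, mean, sem`.
#' @export
condition_summary <- function(summaries, statistics = NULL) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0L) {
    stop_ionopattern("empty_group", "no embryos to summarize")
  }
  statistics <- statistics %||% summary_statistics(summaries)
  out <- list()
  for (cond in unique(summaries$condition)) {
    sub <- summaries[summaries$condition == cond, , drop = FALSE]
    for (st in statistics) {
      v <- sub[[st]]
      v <- v[!is.na(v)]
      n <- length(v)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, statistic = st, n_embryos = n,
        mean = if (n > 0L) mean(v) else NA_real_,
        sem = if (n > 1L) sd(v) / sqrt(n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Compare test conditions against a reference condition
#'
#' For every statistic and every test condition: the percent change of group
#' means, a two-tailed Welch t-test over the per-embryo values, and the
#' significance tier. Statistics for which either group has fewer than two
#' defined values get `NA` test fields.
#'
#' @param summaries Per-embryo summary table from [summarize_cohort()].
#' @param reference Reference condition label.
#' @param tests Character vector of test condition labels.
#' @param statistics Summary columns to contrast; default all numeric
#'   statistics.
#' @return Data.frame with one row per (statistic, test condition):
#'   `statistic, reference, test, ref_mean, test_mean, percent_change, t,
#'   df, p, tier`.
#' @export
compare_conditions <- function(summaries, reference, tests,
                               statistics = NULL) {
  stopifnot(is.data.frame(summaries))
  conds <- unique(summaries$condition)
  missing <- setdiff(c(reference, tests), conds)
  if (length(missing) > 0L) {
    stop_ionopattern("lookup_error", "unknown condition label(s): %s",
                     paste(missing, collapse = ", "))
  }
  statistics <- statistics %||% summary_statistics(summaries)
  ref_rows <- summaries[summaries$condition == reference, , drop = FALSE]
  out <- list()
  for (test in tests) {
    test_rows <- summaries[summaries$condition == test, , drop = FALSE]
    for (st in statistics) {
      a <- ref_rows[[st]]; a <- a[!is.na(a)]
      b <- test_rows[[st]]; b <- b[!is.na(b)]
      pc <- if (length(a) > 0L && length(b) > 0L && mean(a) != 0) {
        percent_change(mean(a), mean(b))
      } else NA_real_
      if (length(a) >= 2L && length(b) >= 2L) {
        w <- welch_t_test(b, a) # t > 0 means test > reference
        t_v <- w$t; df_v <- w$df; p_v <- w$p
      } else {
        t_v <- df_v <- p_v <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        statistic = st, reference = reference, test = test,
        ref_mean = if (length(a)) mean(a) else NA_real_,
        test_mean = if (length(b)) mean(b) else NA_real_,
        percent_change = pc, t = t_v, df = df_v, p = p_v,
        tier = significance_tier(p_v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
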
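# Closed-form group-comparison statistics from summary data. These reproduce
# raw-data one-way ANOVA / Pearson chi-square exactly when the summaries are
# exact, and are the bridge between the package and published cohort tables
# for which raw data are unavailable.

#' Construct per-group summary records
#'
#' @param label Character vector of group labels.
#' @param n Integer vector of group sizes (each >= 2).
#' @param mean,sd Numeric vectors of group means and standard deviations
#'   (sd >= 0, computed with the n-1 denominator).
#' @return A `data.frame` with class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (length(unique(c(length(label), length(n), length(mean), length(sd)))) != 1L)
    stop_mse("group_summary fields must have equal length", "mse_bad_argument")
  for (i in seq_along(n)) {
    check_number(n[i], "n", lower = 2, integer = TRUE)
    check_number(sd[i], "sd", lower = 0)
    check_number(mean[i], "mean")
  }
  structure(data.frame(label = as.character(label), n = as.integer(n),
                       mean = as.numeric(mean), sd = as.numeric(sd),
                       stringsAsFactors = FALSE),
            class = c("group_summary", "data.frame"))
}

#' One-way ANOVA from group summary statistics
#'
#' Decomposes the total sum of squares into between- and within-group parts
#' using only (n, mean, sd) per group: SSB = sum n_i (m_i - grand)^2,
#' SSW = sum (n_i - 1) sd_i^2. Identical to a raw-data one-way ANOVA when the
#' summaries are exact.
#'
#' @param groups A `group_summary` (or data.frame with columns n, mean, sd).
#' @return List with `F`, `df_between`, `df_within`, `eta_sq`, `p`.
#' @export
anova_from_summary <- function(groups) {
  if (nrow(groups) < 2L)
    stop_mse("need at least two groups", "mse_bad_argument")
  n <- groups$n; m <- groups$mean; s <- groups$sd
  N <- sum(n)
  if (N <= nrow(groups))
    stop_mse("total n must exceed the number of groups", "mse_bad_argument")
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- nrow(groups) - 1L
  df2 <- N - nrow(groups)
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, df_between = df1, df_within = df2,
       eta_sq = ssb / (ssb + ssw),
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square test of independence for a contingency table
#'
#' Uncorrected (no continuity correction): chi2 = sum (O - E)^2 / E with
#' expected counts from the product of margins over the total.
#'
#' @param table Matrix of nonnegative counts with all margins > 0.
#' @return List with `chi_sq`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_mse("counts must be nonnegative integers", "mse_bad_argument")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_mse("all margins must be positive", "mse_zero_margin")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  chi <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(chi_sq = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE), expected = E)
}

#' Pooled mean and standard deviation from group summaries
#'
#' Pooled variance uses the full decomposition (SSB + SSW) / (N - 1), i.e. the
#' variance of the concatenated raw data, not the within-group average.
#'
#' @inheritParams anova_from_summary
#' @return List with `mean` and `sd`.
#' @export
pooled_moments <- function(groups) {
  n <- groups$n; m <- groups$mean; s <- groups$sd
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  list(mean = grand, sd = sqrt((ssb + ssw) / (N - 1)))
}

#' Marginal category percentage from a contingency table
#'
#' @param table Matrix of counts with named rows.
#' @param category Row name whose margin is expressed as a percentage of the
#'   table total.
#' @return Percentage in [0, 100].
#' @export
category_proportion <- function(table, category) {
  table <- as.matrix(table)
  if (!category %in% rownames(table))
    stop_mse(sprintf("unknown category '%s'", category), "mse_bad_argument")
  100 * sum(table[category, ]) / sum(table)
}

#' Reference summary statistics of a multi-country aging and dementia cohort
#'
#' Printed group-level summaries (n = 2211; healthy controls, Alzheimer's
#' disease, frontotemporal lobar degeneration from six Latin American
#' countries) used as worked-example inputs for the summary-statistic module:
#' per-group (n, mean, sd) for age and the three clinical instruments, plus
#' the sex-by-group contingency table. Values are transcribed from a published
#' cohort characterization table; means/SDs are rounded to two decimals as
#' printed.
#'
#' @return List with elements `age`, `cognition`, `functional_ability`,
#'   `neuropsychiatric` (each a [group_summary()]) and `sex` (2x3 count
#'   matrix, rows F/M, columns HC/AD/FTLD).
#' @export
cohort_reference_summaries <- function() {
  g <- c("HC", "AD", "FTLD")
  list(
    age = group_summary(g, c(1175, 781, 255),
                        c(60.21, 70.50, 67.02), c(11.62, 8.40, 7.78)),
    cognition = group_summary(g, c(1175, 781, 255),
                              c(27.50, 20.93, 21.25), c(2.90, 4.41, 6.05)),
    functional_ability = group_summary(g, c(1175, 781, 255),
                                       c(0.20, 12.16, 13.69), c(1.11, 8.11, 9.14)),
    neuropsychiatric = group_summary(g, c(1175, 781, 255),
                                     c(1.45, 6.57, 10.48), c(2.90, 5.71, 7.02)),
    sex = matrix(c(858, 317, 494, 287, 130, 125), nrow = 2,
                 dimnames = list(c("F", "M"), g))
  )
}
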
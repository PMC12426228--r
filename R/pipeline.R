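# End-to-end conveniences tying the modules together, and the analysis-table
# writer used by the command-line interface.

#' Score a raw item table into dimension composites
#'
#' Imputation (chained PMM) followed by min-max scaling and dimension
#' averaging; the standard path from questionnaire to SEM input.
#'
#' @param items data.frame of raw item responses (NAs allowed).
#' @param meta An [item_meta()].
#' @param weights Optional per-item weights (default equal).
#' @param k_donors,n_iterations,seed Imputation settings, see
#'   [impute_chained_pmm()].
#' @param subject_id Optional identifiers.
#' @param ... Further arguments to [impute_chained_pmm()].
#' @return A `dimension_scores` data.frame.
#' @export
score_items <- function(items, meta, weights = NULL, k_donors = 5,
                        n_iterations = 10, seed = 1, subject_id = NULL, ...) {
  use <- meta$item_id[!meta$excluded & meta$item_id %in% names(items)]
  tab <- items[, use, drop = FALSE]
  if (anyNA(tab))
    tab <- impute_chained_pmm(tab, k_donors = k_donors,
                              n_iterations = n_iterations, seed = seed, ...)
  compute_dimension_scores(tab, meta, weights = weights,
                           subject_id = subject_id)
}

#' Assemble the SEM analysis table from scores and raw outcomes
#'
#' Joins dimension scores with outcomes, inverting functional ability and
#' neuropsychiatric symptoms (so all outcomes point "higher = better") and
#' min-max scaling each outcome to [0, 1].
#'
#' @param scores A `dimension_scores` data.frame.
#' @param outcomes data.frame with `subject_id` and the three raw instrument
#'   scores.
#' @param instrument_max Named upper bounds.
#' @return data.frame ready for [sem_mse()] / [bootstrap_effects()].
#' @export
prepare_analysis_table <- function(scores, outcomes,
                                   instrument_max = c(cognition = 30,
                                                      functional_ability = 30,
                                                      neuropsychiatric = 36)) {
  df <- merge(scores, outcomes, by = "subject_id", sort = FALSE)
  for (k in c("functional_ability", "neuropsychiatric"))
    df[[k]] <- invert_outcome(df[[k]], instrument_max[k])
  for (k in mse_outcomes()) {
    rng <- range(df[[k]])
    df[[k]] <- if (rng[1] == rng[2]) 0 else (df[[k]] - rng[1]) / (rng[2] - rng[1])
  }
  df
}
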
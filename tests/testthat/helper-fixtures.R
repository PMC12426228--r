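# Shared in-code fixtures. Everything is generated; nothing is stored.

small_cohort_spec <- function(n = c(HC = 120, AD = 90, FTLD = 40),
                              total_items = 30, seed = 11, ...) {
  cohort_spec(n_per_group = n,
              item_counts = msexposome:::default_item_counts(total_items),
              seed = seed, ...)
}

# Analysis-ready table (dimension scores + scaled outcomes) straight from
# the standardized generator, bypassing the questionnaire layer.
analysis_table <- function(n, loadings = msexposome:::default_loadings(),
                           paths = c(cognition = 0.261,
                                     functional_ability = 0.079,
                                     neuropsychiatric = 0.105),
                           seed = 1) {
  simulate_indicator_data(n, loadings, paths, seed = seed)
}

# Projected (proximal) gradient lasso oracle: ISTA on standardized data.
ista_lasso <- function(Xs, yc, lambda, iters = 50000L) {
  n <- nrow(Xs)
  L <- max(eigen(crossprod(Xs) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  b <- numeric(ncol(Xs))
  for (i in seq_len(iters)) {
    g <- crossprod(Xs, yc - Xs %*% b) / n
    u <- b + g / L
    bn <- sign(u) * pmax(abs(u) - lambda / L, 0)
    if (max(abs(bn - b)) < 1e-13) { b <- bn; break }
    b <- bn
  }
  b
}

lasso_objective <- function(Xs, yc, b, lambda) {
  sum((yc - Xs %*% b)^2) / (2 * nrow(Xs)) + lambda * sum(abs(b))
}
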
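# Multiple imputation by chained equations with predictive mean matching.
# One completed dataset is produced (the modelling pipeline imputes once
# before covariance-structure estimation). Matching is type-0: regression
# predictions are deterministic (ridge-stabilized least squares) and the
# stochastic element is the draw among the k nearest donors, so every imputed
# cell equals an observed value of the same item.

ridge_lm_predict <- function(X, y, newX, ridge = 1e-6) {
  # Least squares with a tiny ridge on standardized predictors; tolerant of
  # collinear or constant columns, deterministic.
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd)
  sx[sx == 0] <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  Ns <- sweep(sweep(newX, 2, mx), 2, sx, "/")
  A <- crossprod(Xs) + diag(ridge * nrow(Xs), ncol(Xs))
  b <- solve(A, crossprod(Xs, y - mean(y)))
  list(fit = mean(y) + as.numeric(Xs %*% b),
       pred = mean(y) + as.numeric(Ns %*% b))
}

#' Chained predictive-mean-matching imputation
#'
#' Iterates over incomplete items in order of ascending missingness. For each
#' item, a linear model of the observed values on all other (currently
#' completed) items yields predictions; each missing cell receives the
#' observed value of one of the `k_donors` donors whose predictions are
#' closest to its own (ties broken by donor order, donor drawn uniformly).
#' Initial fill is a random draw from the item's observed values. Imputed
#' values therefore never leave an item's observed support.
#'
#' @param table data.frame of item responses (numeric columns; NAs mark
#'   missing cells). Non-numeric columns are not allowed.
#' @param k_donors Number of candidate donors (default 5).
#' @param n_iterations Chained passes over all incomplete items (default 10).
#' @param seed Integer seed; imputation is deterministic given the seed.
#' @param predictors `"all"` (default) regresses on every other item;
#'   `"dimension_means"` uses per-dimension means of the other items (requires
#'   `meta`), a standard reduction for very wide questionnaires.
#' @param meta Optional [item_meta()] for `predictors = "dimension_means"`.
#' @return The completed data.frame (no missing cells), with attribute
#'   `imputed_cells` (logical matrix).
#' @export
impute_chained_pmm <- function(table, k_donors = 5, n_iterations = 10, seed = 1,
                               predictors = c("all", "dimension_means"),
                               meta = NULL) {
  predictors <- match.arg(predictors)
  check_number(k_donors, "k_donors", lower = 1, integer = TRUE)
  check_number(n_iterations, "n_iterations", lower = 1, integer = TRUE)
  tab <- as.data.frame(table)
  num <- vapply(tab, is.numeric, TRUE)
  if (!all(num))
    stop_mse("all item columns must be numeric", "mse_bad_argument")
  miss <- is.na(as.matrix(tab))
  if (!any(miss)) return(table)
  n_obs <- colSums(!miss)
  fully_missing <- names(tab)[n_obs == 0]
  if (length(fully_missing))
    stop_mse(sprintf("item(s) fully missing, unimputable: %s",
                     paste(fully_missing, collapse = ", ")),
             "mse_unimputable_item")
  short <- names(tab)[n_obs < k_donors & colSums(miss) > 0]
  if (length(short))
    stop_mse(sprintf("k_donors = %d exceeds observed count for: %s",
                     k_donors, paste(short, collapse = ", ")),
             "mse_too_few_donors")

  visit <- names(tab)[colSums(miss) > 0]
  visit <- visit[order(colSums(miss)[visit])]    # ascending missingness

  with_seed(substream_seed(seed, "pmm"), {
    # initial fill: random observed value of the same item
    for (v in visit) {
      obs <- tab[[v]][!miss[, v]]
      tab[[v]][miss[, v]] <- sample(obs, sum(miss[, v]), replace = TRUE)
    }
    for (iter in seq_len(n_iterations)) {
      for (v in visit) {
        mrows <- miss[, v]
        others <- setdiff(names(tab), v)
        if (predictors == "dimension_means") {
          if (is.null(meta))
            stop_mse("`meta` required for dimension_means predictors",
                     "mse_bad_argument")
          X <- dimension_mean_design(tab, meta, exclude = v)
        } else {
          X <- as.matrix(tab[, others, drop = FALSE])
        }
        pr <- ridge_lm_predict(X[!mrows, , drop = FALSE], tab[[v]][!mrows],
                               X[mrows, , drop = FALSE])
        donors_y <- tab[[v]][!mrows]
        donors_fit <- pr$fit
        for (ii in seq_len(sum(mrows))) {
          d <- order(abs(donors_fit - pr$pred[ii]))[seq_len(min(k_donors,
                                                               length(donors_y)))]
          pick <- if (length(d) == 1L) d else d[sample.int(length(d), 1L)]
          tab[[v]][which(mrows)[ii]] <- donors_y[pick]
        }
      }
    }
  })
  attr(tab, "imputed_cells") <- miss
  tab
}

dimension_mean_design <- function(tab, meta, exclude) {
  dims <- unique(meta$dimension)
  out <- matrix(0, nrow(tab), length(dims), dimnames = list(NULL, dims))
  for (d in dims) {
    ids <- setdiff(meta$item_id[meta$dimension == d], exclude)
    ids <- intersect(ids, names(tab))
    out[, d] <- if (length(ids)) rowMeans(tab[, ids, drop = FALSE]) else 0
  }
  out[, colSums(abs(out)) > 0, drop = FALSE]
}
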
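# Per-subject factor scores (the "global MSE score"), modification indices,
# and the case-resampling bootstrap of standardized structural paths.

#' Extract per-subject latent exposome factor scores
#'
#' Regression-method scores are the conditional expectation of the latent
#' given the observed variables under the fitted Gaussian model:
#' E[eta | z] = Cov(eta, z) Sigma^-1 (z - mean). Bartlett scores use the
#' measurement weighting (L' Theta^-1 L)^-1 L' Theta^-1 (z - mean) and are an
#' affine transform of the regression scores for one factor.
#'
#' @param data data.frame with the fit's observed variables (complete rows);
#'   defaults to the data stored by [sem_mse()].
#' @param fit A converged `sem_fit`.
#' @param method `"regression"` (default) or `"bartlett"`.
#' @return data.frame with `subject_id` (row names or index) and `score`;
#'   attribute `method`.
#' @export
extract_factor_scores <- function(fit, data = fit$data,
                                  method = c("regression", "bartlett")) {
  method <- match.arg(method)
  if (is.null(data))
    stop_mse("no data: pass `data` or fit with sem_mse()", "mse_bad_argument")
  if (!fit$converged)
    warning("extracting scores from a non-converged fit", call. = FALSE)
  obs <- fit$model$obs
  X <- as.matrix(data[, obs, drop = FALSE])
  if (anyNA(X))
    stop_mse("factor scores require complete data", "mse_missing_values")
  ctr <- sweep(X, 2, fit$means %||% colMeans(X))
  if (method == "regression") {
    cov_eta_z <- fit$implied_full[fit$model$eta, seq_len(fit$model$p)]
    w <- solve(fit$Sigma, cov_eta_z)
    score <- as.numeric(ctr %*% w)
  } else {
    if (length(fit$spec$covariates))
      stop_mse("Bartlett scores unsupported with exogenous covariates",
               "mse_bad_argument")
    pt <- fit$param
    L <- pt$est[pt$matrix == "A"]
    names(L) <- pt$lhs[pt$matrix == "A"]
    L <- L[obs]
    Theta <- matrix(0, length(obs), length(obs),
                    dimnames = list(obs, obs))
    for (r in which(pt$matrix == "S" & pt$lhs != ".eta" & pt$rhs != ".eta")) {
      Theta[pt$lhs[r], pt$rhs[r]] <- pt$est[r]
      Theta[pt$rhs[r], pt$lhs[r]] <- pt$est[r]
    }
    Ti <- solve(Theta)
    w <- as.numeric(solve(t(L) %*% Ti %*% L) %*% t(L) %*% Ti)
    score <- as.numeric(ctr %*% w)
  }
  out <- data.frame(subject_id = rownames(data) %||% seq_len(nrow(data)),
                    score = score, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

#' Modification index for a currently constrained parameter
#'
#' Score (Lagrange-multiplier) statistic approximating the chi-square drop
#' from freeing one constrained parameter, computed from the gradient and
#' expected information of the ML discrepancy on the parameter set augmented
#' with the candidate: MI = (n - 1)/2 g' H^-1 g.
#'
#' @param fit A converged `sem_fit`.
#' @param pair Character vector of two distinct observed variable names whose
#'   residual covariance is the candidate (must not already be free).
#' @return The MI value (>= 0 up to numerical error).
#' @export
modification_index <- function(fit, pair) {
  model <- fit$model
  if (length(pair) != 2L || !all(pair %in% model$obs) || pair[1] == pair[2])
    stop_mse("`pair` must name two distinct observed variables", "mse_bad_argument")
  i <- model$idx[pair[1]]; j <- model$idx[pair[2]]
  pt <- model$param_table
  already <- any(pt$mat == "S" & ((pt$i == i & pt$j == j) |
                                    (pt$i == j & pt$j == i)) & pt$free)
  if (already)
    stop_mse("candidate parameter is already free", "mse_already_free")
  st <- sigma_of_theta(model, fit$theta)
  extra <- data.frame(mat = "S", i = i, j = j, free = TRUE, value = 0,
                      label = paste0("cand_", pair[1], "_", pair[2]),
                      stringsAsFactors = FALSE)
  derivs <- sigma_derivatives(model, st, extra = extra)
  Sinv <- chol2inv(chol(st$Sigma))
  W <- Sinv - Sinv %*% fit$S %*% Sinv
  g <- vapply(derivs, function(D) sum(W * D), 1)
  m <- length(derivs)
  H <- matrix(0, m, m)
  SD <- lapply(derivs, function(D) Sinv %*% D)
  for (a in seq_len(m)) for (b in a:m)
    H[a, b] <- H[b, a] <- sum(t(SD[[a]]) * SD[[b]])
  mi <- (fit$n - 1) / 2 * as.numeric(t(g) %*% solve(H, g))
  max(mi, 0)
}

#' Rank all constrained residual covariances by modification index
#'
#' @param fit A `sem_fit`.
#' @param within `"all"` (default) or `"indicators"`.
#' @return data.frame sorted by decreasing MI.
#' @export
modification_indices <- function(fit, within = c("all", "indicators")) {
  within <- match.arg(within)
  vars <- if (within == "indicators") fit$spec$indicators else fit$model$obs
  res <- list()
  for (a in seq_along(vars)) for (b in seq_along(vars)) {
    if (b <= a) next
    mi <- tryCatch(modification_index(fit, c(vars[a], vars[b])),
                   mse_already_free = function(e) NA_real_)
    res[[length(res) + 1L]] <- data.frame(var1 = vars[a], var2 = vars[b],
                                          mi = mi, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out[order(-out$mi), ]
}

#' Case-resampling bootstrap of standardized structural paths
#'
#' Resamples subjects with replacement, refits the SEM on each replicate, and
#' collects the standardized path toward each outcome. Non-converged
#' replicates are excluded and counted; more than 20% failures is a hard
#' error.
#'
#' @param data Subject-level data.frame with the spec's observed variables.
#' @param spec A [sem_spec()].
#' @param B Number of bootstrap replicates (>= 2; 400 in the reference
#'   analysis).
#' @param seed Integer seed (replicate draws are reproducible).
#' @return Object of class `sem_bootstrap`: matrix `paths` (B_ok x outcomes)
#'   of standardized paths, `n_failed`, `indices` (resample index matrix),
#'   and percentile `ci` (2.5/97.5%).
#' @export
bootstrap_sem <- function(data, spec = sem_spec(), B = 400, seed = 1) {
  check_number(B, "B", lower = 2, integer = TRUE)
  n <- nrow(data)
  idx <- with_seed(substream_seed(seed, "bootstrap-sem"), {
    matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  })
  res <- matrix(NA_real_, B, length(spec$outcomes),
                dimnames = list(NULL, spec$outcomes))
  failed <- 0L
  for (b in seq_len(B)) {
    fit <- tryCatch(sem_mse(data[idx[b, ], , drop = FALSE], spec),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      failed <- failed + 1L
    } else {
      res[b, ] <- fit$paths$std[match(spec$outcomes, fit$paths$lhs)]
    }
  }
  if (failed > 0.2 * B)
    stop_mse(sprintf("%d/%d bootstrap replicates failed to converge", failed, B),
             "mse_bootstrap_failure")
  paths <- res[stats::complete.cases(res), , drop = FALSE]
  ci <- apply(paths, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(paths = paths, n_failed = failed, B = B, indices = idx,
                 ci = ci, spec = spec),
            class = "sem_bootstrap")
}
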
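# Paired bootstrap of the cumulative (latent) exposome effect against the
# individual-dimension Lasso effect, and the fixed-effect meta-regression
# that compares them (the Table-2-shaped analysis surface).

#' Paired bootstrap of global-score and individual-dimension effects
#'
#' For each bootstrap replicate the SAME resampled subjects feed both model
#' families: the SEM standardized path from the latent exposome factor to
#' each outcome (global arm) and the in-sample R-squared of a Lasso of that
#' outcome on the ten dimension scores (individual arm). The Lasso penalty is
#' selected once on the full sample by cross-validation and reused within
#' replicates (config: `reselect_lambda = TRUE` re-runs CV per replicate).
#' Outcomes and predictors are min-max scaled to [0, 1] before the Lasso to
#' match the scoring convention.
#'
#' @param data data.frame with the dimension scores and outcomes named by
#'   `sem_spec_obj`.
#' @param sem_spec_obj A [sem_spec()].
#' @param B Replicates (default 400).
#' @param seed Integer seed.
#' @param n_folds CV folds for the penalty selection.
#' @param reselect_lambda Re-run CV inside every replicate (slow; default
#'   FALSE).
#' @return Object of class `replicate_effects`: long data.frame `effects`
#'   (replicate, outcome, model_type, effect), `n_failed`, `B`.
#' @export
bootstrap_effects <- function(data, sem_spec_obj = sem_spec(), B = 400,
                              seed = 1, n_folds = 10,
                              reselect_lambda = FALSE) {
  check_number(B, "B", lower = 2, integer = TRUE)
  outs <- sem_spec_obj$outcomes
  dims <- sem_spec_obj$indicators
  n <- nrow(data)
  sc01 <- function(v) (v - min(v)) / (max(v) - min(v))
  Xd <- as.data.frame(lapply(data[, dims, drop = FALSE], sc01))
  Yd <- as.data.frame(lapply(data[, outs, drop = FALSE], sc01))

  lam <- stats::setNames(vapply(outs, function(k) {
    fit_lasso_cv(Xd, Yd[[k]], n_folds = n_folds, seed = seed)$lambda
  }, 1), outs)

  idx <- with_seed(substream_seed(seed, "bootstrap-effects"),
                   matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
  rows <- list()
  failed <- 0L
  for (b in seq_len(B)) {
    take <- idx[b, ]
    fit <- tryCatch(sem_mse(data[take, , drop = FALSE], sem_spec_obj),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      failed <- failed + 1L
      next
    }
    beta <- fit$paths$std[match(outs, fit$paths$lhs)]
    for (ki in seq_along(outs)) {
      k <- outs[ki]
      lf <- tryCatch({
        if (reselect_lambda) {
          fit_lasso_cv(Xd[take, , drop = FALSE], Yd[[k]][take],
                       n_folds = n_folds, seed = seed)
        } else {
          fit_lasso_cv(Xd[take, , drop = FALSE], Yd[[k]][take],
                       lambda = lam[k])
        }
      }, error = function(e) NULL)
      if (is.null(lf)) next
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = b, outcome = k,
        model_type = c("global_MSE", "individual_dimensions"),
        effect = c(beta[ki], lf$metrics$r_squared),
        stringsAsFactors = FALSE)
    }
  }
  if (failed > 0.2 * B)
    stop_mse(sprintf("%d/%d bootstrap replicates failed", failed, B),
             "mse_bootstrap_failure")
  structure(list(effects = do.call(rbind, rows), n_failed = failed, B = B,
                 indices = idx, lambda = lam),
            class = "replicate_effects")
}

#' Fixed-effect meta-regression comparing the two model families
#'
#' Treats each arm's bootstrap draws as effect estimates with a common
#' per-replicate sampling variance equal to the arm's empirical variance
#' (config `weighting = "equal"` forces unit weights; identical pooling under
#' constant within-arm variances). The common effect per arm is then the
#' inverse-variance weighted (= arithmetic) mean with standard error
#' sqrt(v / B); the model-type moderator is tested by the Wald chi-square
#' QM = (mean_1 - mean_2)^2 / (v_1/B_1 + v_2/B_2) on 1 df.
#'
#' @param effects A `replicate_effects` or its long `effects` data.frame.
#' @param weighting `"empirical"` (default) or `"equal"`.
#' @return data.frame, one row per outcome x model_type with columns
#'   `common_effect`, `ci_lower`, `ci_upper`, `qm`, `p` (QM and p repeated
#'   across the pair).
#' @export
meta_compare <- function(effects, weighting = c("empirical", "equal")) {
  weighting <- match.arg(weighting)
  eff <- if (inherits(effects, "replicate_effects")) effects$effects else effects
  out <- list()
  for (k in unique(eff$outcome)) {
    sub <- eff[eff$outcome == k, ]
    arms <- split(sub$effect, sub$model_type)
    if (length(arms) != 2L || any(vapply(arms, length, 1L) < 2L))
      stop_mse("need >= 2 replicates in each of two arms", "mse_bad_argument")
    mns <- vapply(arms, mean, 1)
    vars <- vapply(arms, stats::var, 1)
    Bs <- vapply(arms, length, 1L)
    if (all(vars == 0))
      stop_mse("zero variance in both arms", "mse_degenerate_outcome")
    sev <- if (weighting == "empirical") vars / Bs else
      rep(sum(vars * (Bs - 1)) / (sum(Bs) - 2) / mean(Bs), 2)
    qm <- (mns[1] - mns[2])^2 / sum(vars / Bs)
    for (a in names(arms)) {
      se <- sqrt(sev[a])
      out[[length(out) + 1L]] <- data.frame(
        outcome = k, model_type = a, common_effect = mns[a],
        ci_lower = mns[a] - 1.96 * se, ci_upper = mns[a] + 1.96 * se,
        n_replicates = Bs[a], qm = qm,
        p = stats::pchisq(qm, 1, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
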
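# L1-penalized regression of each outcome on the ten dimension scores, by
# cyclic coordinate descent with an active-set strategy. The objective is
#   (1 / 2n) ||y - b0 - X b||^2 + lambda ||b||_1
# on internally standardized predictors (coefficients are reported on that
# standardized-X scale). Written in-package so the Karush-Kuhn-Tucker
# certificate the downstream comparison relies on is under direct control.

# Covariance-form cyclic coordinate descent: with G = X'X/n and c = X'y/n
# precomputed, each coordinate update costs O(k) independent of n.
lasso_cd_cov <- function(G, cvec, lambda, b_init = NULL, tol = 1e-12,
                         max_iter = 100000L) {
  k <- length(cvec)
  b <- b_init %||% numeric(k)
  g <- cvec - as.numeric(G %*% b)          # current gradient of the smooth part
  d <- diag(G)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(k)) {
      rho <- g[j] + d[j] * b[j]
      bn <- sign(rho) * max(abs(rho) - lambda, 0) / d[j]
      step <- bn - b[j]
      if (step != 0) {
        g <- g - G[, j] * step
        b[j] <- bn
        delta <- max(delta, abs(step))
      }
    }
    if (delta < tol) break
  }
  b
}

lasso_cd <- function(Xs, yc, lambda, b_init = NULL, tol = 1e-12,
                     max_iter = 100000L) {
  n <- nrow(Xs)
  lasso_cd_cov(crossprod(Xs) / n, as.numeric(crossprod(Xs, yc)) / n, lambda,
               b_init = b_init, tol = tol, max_iter = max_iter)
}

#' Lasso with penalty selection by k-fold cross-validation
#'
#' Predictors are standardized to mean 0, SD 1 internally; the outcome is
#' used as supplied (scale it to [0, 1] upstream to match the scoring
#' convention). The penalty grid is 100 log-spaced points from lambda_max
#' (the smallest penalty with an all-zero solution) down four decades;
#' lambda is chosen by minimum mean cross-validated squared error. Solutions
#' satisfy the KKT conditions to within ~1e-10.
#'
#' @param X Matrix/data.frame of predictors (dimension scores).
#' @param y Numeric outcome.
#' @param n_folds Folds for cross-validation (default 10).
#' @param lambda_grid Optional decreasing penalty grid; default as above.
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @return Object of class `lasso_fit`: `coefficients` (standardized-X
#'   scale), `intercept`, `lambda`, `lambda_grid`, `cv_error`, `metrics`
#'   (in-sample, via [prediction_metrics()]), scaling constants.
#' @export
fit_lasso_cv <- function(X, y, n_folds = 10, lambda_grid = NULL, seed = 1,
                         lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop_mse("length(y) != nrow(X)", "mse_bad_argument")
  if (stats::sd(y) == 0) stop_mse("constant outcome", "mse_degenerate_outcome")
  if (is.null(lambda) && n < n_folds)
    stop_mse("fewer observations than folds", "mse_bad_argument")
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  if (any(sx == 0)) stop_mse("constant predictor column", "mse_bad_argument")
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y); yc <- y - my

  G <- crossprod(Xs) / n
  cvec <- as.numeric(crossprod(Xs, yc)) / n
  lambda_max <- max(abs(cvec))
  if (is.null(lambda_grid))
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                           length.out = 100))
  cv_err <- NULL
  if (is.null(lambda)) {
    folds <- with_seed(substream_seed(seed, "lasso-folds"),
                       sample(rep_len(seq_len(n_folds), n)))
    errs <- matrix(NA_real_, n_folds, length(lambda_grid))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      Xtr <- Xs[tr, , drop = FALSE]; ytr <- yc[tr]
      mtr <- mean(ytr)
      Gtr <- crossprod(Xtr) / sum(tr)
      ctr <- as.numeric(crossprod(Xtr, ytr - mtr)) / sum(tr)
      Xte <- Xs[!tr, , drop = FALSE]; yte <- yc[!tr]
      b <- numeric(ncol(Xs))
      for (li in seq_along(lambda_grid)) {     # warm starts down the path
        b <- lasso_cd_cov(Gtr, ctr, lambda_grid[li], b_init = b)
        errs[f, li] <- mean((yte - mtr - Xte %*% b)^2)
      }
    }
    cv_err <- colMeans(errs)
    lambda <- lambda_grid[which.min(cv_err)]
  }
  b <- lasso_cd_cov(G, cvec, lambda)
  names(b) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  fit <- structure(list(coefficients = b, intercept = my, lambda = lambda,
                        lambda_grid = lambda_grid, cv_error = cv_err,
                        center_x = mx, scale_x = sx, center_y = my),
                   class = "lasso_fit")
  fit$metrics <- prediction_metrics(fit, X, y)
  fit
}

#' Predict from a lasso fit
#'
#' @param object A `lasso_fit`.
#' @param newdata Predictor matrix on the original scale.
#' @param ... Unused.
#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center_x), 2,
              object$scale_x, "/")
  as.numeric(object$intercept + Xs %*% object$coefficients)
}

#' Maximum KKT violation of a lasso solution
#'
#' For the objective (1/2n)||y - b0 - Xb||^2 + lambda||b||_1 on the
#' standardized predictors: active coordinates must satisfy
#' x_j' r / n = lambda sign(b_j) and inactive ones |x_j' r / n| <= lambda.
#' Returns the largest violation across coordinates (0 at an exact solution).
#'
#' @param fit A `lasso_fit`.
#' @param X,y The data the fit was computed on.
#' @return Nonnegative scalar.
#' @export
lasso_kkt_residual <- function(fit, X, y) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$center_x), 2, fit$scale_x, "/")
  r <- y - fit$intercept - Xs %*% fit$coefficients
  g <- as.numeric(crossprod(Xs, r)) / nrow(Xs)
  b <- fit$coefficients
  viol <- ifelse(b != 0, abs(g - fit$lambda * sign(b)),
                 pmax(abs(g) - fit$lambda, 0))
  max(viol)
}

#' Fit metrics: R-squared, Cohen's f-squared, mean squared error, MAE
#'
#' R2 = 1 - SSE/SST on the supplied data; f2 = R2 / (1 - R2) (undefined with
#' a flag at R2 = 1); MnSqErr and MAE on the outcome's scale.
#'
#' @param fit A `lasso_fit` (or any object with a `predict` method).
#' @param X,y Evaluation data (same scaling as at fit time).
#' @return List `r_squared`, `f_squared`, `mse`, `mae`, `f_squared_defined`.
#' @export
prediction_metrics <- function(fit, X, y) {
  pred <- stats::predict(fit, X)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_mse("zero outcome variance", "mse_degenerate_outcome")
  sse <- sum((y - pred)^2)
  r2 <- 1 - sse / sst
  defined <- r2 < 1
  list(r_squared = r2,
       f_squared = if (defined) r2 / (1 - r2) else Inf,
       mse = mean((y - pred)^2), mae = mean(abs(y - pred)),
       f_squared_defined = defined)
}

#' Cohen's f-squared from a coefficient of determination
#'
#' @param r_squared R-squared in [0, 1).
#' @return R2 / (1 - R2).
#' @export
cohens_f2 <- function(r_squared) {
  check_number(r_squared, "r_squared", lower = 0, upper = 1 - 1e-15)
  r_squared / (1 - r_squared)
}
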
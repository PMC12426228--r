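# Maximum-likelihood estimation of the covariance structure, standardized
# solution, and fit indices.

start_values <- function(model, S) {
  # Loadings from one round of principal-axis factoring on the indicator
  # block (communalities = squared multiple correlations), rescaled so the
  # fixed indicator's loading is 1; residual variances at half the observed
  # variances; covariate block at its sample values.
  spec <- model$spec
  pt <- model$param_table
  theta <- numeric(model$q)
  ind <- spec$indicators
  Si <- S[ind, ind, drop = FALSE]
  h2 <- tryCatch({
    R <- stats::cov2cor(Si)
    smc <- 1 - 1 / diag(solve(R))
    smc * diag(Si)
  }, error = function(e) 0.5 * diag(Si))
  Sr <- Si
  diag(Sr) <- h2
  ev <- eigen(Sr, symmetric = TRUE)
  l <- ev$vectors[, 1] * sqrt(max(ev$values[1], 1e-6))
  names(l) <- ind
  if (abs(l[spec$fixed_indicator]) < 1e-6)
    l[spec$fixed_indicator] <- sqrt(max(h2[spec$fixed_indicator], 0.1))
  if (l[spec$fixed_indicator] < 0) l <- -l
  psi0 <- l[spec$fixed_indicator]^2
  lam0 <- l / l[spec$fixed_indicator]

  free <- which(pt$free)
  for (k in seq_along(free)) {
    r <- free[k]
    lab <- pt$label[r]
    theta[k] <- if (startsWith(lab, "lambda_")) {
      lam0[sub("lambda_", "", lab)]
    } else if (startsWith(lab, "beta_")) {
      v <- sub("beta_", "", lab)
      # moment start: cov(outcome, fixed indicator) ~ beta * psi
      S[v, spec$fixed_indicator] / psi0
    } else if (lab == "psi") {
      psi0
    } else if (startsWith(lab, "theta_")) {
      0.5 * S[sub("theta_", "", lab), sub("theta_", "", lab)]
    } else if (startsWith(lab, "phi_")) {
      ab <- find_pair(lab, "phi_", model$spec$covariates)
      S[ab[1], ab[2]]
    } else if (startsWith(lab, "cov_")) {
      0
    } else if (startsWith(lab, "gamma_")) {
      0
    } else 0
  }
  theta
}

find_pair <- function(label, prefix, pool) {
  body <- sub(prefix, "", label)
  for (a in pool) for (b in pool) {
    if (body == paste(a, b, sep = "_")) return(c(a, b))
  }
  stop_mse(sprintf("cannot parse parameter label '%s'", label), "mse_internal")
}

#' Fit the one-factor structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' F(theta) = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p
#' over the free parameters by quasi-Newton iteration with analytic
#' gradients. The model chi-square is (n - 1) F at the optimum (Joreskog
#' convention); the baseline is the independence model. Standard errors come
#' from the inverse expected information. Negative residual-variance
#' solutions (Heywood cases) are flagged, not clipped, unless
#' `bound_variances = TRUE` imposes nonnegativity.
#'
#' @param S Sample covariance matrix (n - 1 denominator) of the observed
#'   variables, with dimnames covering the spec's variables.
#' @param n Number of subjects (> number of observed variables).
#' @param spec A [sem_spec()].
#' @param bound_variances Lower-bound residual variances at 0 (default FALSE).
#' @param control Passed to [stats::nlminb()] (iteration caps, tolerances).
#' @return Object of class `sem_fit`; see [summary.sem_fit()]. Key fields:
#'   `loadings`, `paths` (data.frames with unstandardized and standardized
#'   estimates, SEs and 95% CIs), `fit_indices`, `chi_sq`, `df`, `q`,
#'   `converged`, `heywood`, `Sigma`, `factor_loadings`.
#' @export
fit_sem_ml <- function(S, n, spec = sem_spec(), bound_variances = FALSE,
                       control = list(iter.max = 10000, eval.max = 20000,
                                      rel.tol = 1e-12)) {
  model <- build_model(spec)
  obs <- model$obs
  if (is.null(dimnames(S)) || !all(obs %in% rownames(S)))
    stop_mse("S must have dimnames covering the model's observed variables",
             "mse_bad_argument")
  S <- as.matrix(S)[obs, obs]
  p <- model$p
  if (n <= p)
    stop_mse("n must exceed the number of observed variables", "mse_bad_argument")
  chS <- tryCatch(chol(S), error = function(e)
    stop_mse("sample covariance is not positive definite", "mse_not_pd"))
  logdetS <- 2 * sum(log(diag(chS)))
  if (model$q > p * (p + 1) / 2)
    stop_mse("model has more free parameters than covariance moments",
             "mse_not_identified")

  obj <- function(theta) {
    st <- tryCatch(sigma_of_theta(model, theta), error = function(e) NULL)
    if (is.null(st)) return(1e10)
    v <- fml_value(S, st$Sigma, logdetS)
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(theta) {
    st <- tryCatch(sigma_of_theta(model, theta), error = function(e) NULL)
    if (is.null(st)) return(numeric(model$q))
    ch <- tryCatch(chol(st$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(numeric(model$q))
    Sinv <- chol2inv(ch)
    W <- Sinv - Sinv %*% S %*% Sinv
    derivs <- sigma_derivatives(model, st)
    vapply(derivs, function(D) sum(W * D), 1)
  }

  lower <- rep(-Inf, model$q)
  if (bound_variances) {
    labs <- model$param_table$label[model$param_table$free]
    lower[startsWith(labs, "theta_") | labs == "psi"] <- 0
  }
  theta0 <- start_values(model, S)
  opt <- stats::nlminb(theta0, obj, gradient = gr, lower = lower,
                       control = control)
  # polish from a jittered restart if the first solve looks poor
  gnorm <- max(abs(gr(opt$par)))
  if (!is.finite(opt$objective) || gnorm > 1e-5) {
    opt2 <- stats::nlminb(theta0 * 0.9 + 0.05, obj, gradient = gr,
                          lower = lower, control = control)
    if (is.finite(opt2$objective) && opt2$objective <= opt$objective) {
      opt <- opt2
      gnorm <- max(abs(gr(opt$par)))
    }
  }

  # Newton polish on the expected information: quasi-Newton solutions can
  # stall at gradient norms ~1e-4 on small samples
  theta <- opt$par
  for (pol in 1:30) {
    if (gnorm < 1e-8) break
    st <- tryCatch(sigma_of_theta(model, theta), error = function(e) NULL)
    if (is.null(st)) break
    ch <- tryCatch(chol(st$Sigma), error = function(e) NULL)
    if (is.null(ch)) break
    Sinv <- chol2inv(ch)
    W <- Sinv - Sinv %*% S %*% Sinv
    derivs <- sigma_derivatives(model, st)
    g <- vapply(derivs, function(D) sum(W * D), 1)
    Hp <- matrix(0, model$q, model$q)
    SDp <- lapply(derivs, function(D) Sinv %*% D)
    for (a in seq_len(model$q)) for (b in a:model$q)
      Hp[a, b] <- Hp[b, a] <- sum(t(SDp[[a]]) * SDp[[b]])
    step <- tryCatch(solve(Hp + diag(1e-10, model$q), g),
                     error = function(e) NULL)
    if (is.null(step)) break
    improved <- FALSE
    for (tt in c(1, 0.5, 0.25, 0.1)) {
      cand <- theta - tt * step
      if (any(cand < lower)) next
      gc2 <- max(abs(gr(cand)))
      if (is.finite(gc2) && gc2 < gnorm && obj(cand) <= obj(theta) + 1e-12) {
        theta <- cand
        gnorm <- gc2
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }

  st <- sigma_of_theta(model, theta)
  fml <- fml_value(S, st$Sigma, logdetS)
  converged <- is.finite(fml) && gnorm < 1e-5

  df <- p * (p + 1) / 2 - model$q
  chi_sq <- (n - 1) * fml
  chi_b <- (n - 1) * (sum(log(diag(S))) - logdetS)
  df_b <- p * (p - 1) / 2

  # expected information and standard errors
  derivs <- sigma_derivatives(model, st)
  Sinv <- chol2inv(chol(st$Sigma))
  q <- model$q
  H <- matrix(0, q, q)
  SD <- lapply(derivs, function(D) Sinv %*% D)
  for (a in seq_len(q)) for (b in a:q) {
    H[a, b] <- H[b, a] <- sum(t(SD[[a]]) * SD[[b]])
  }
  vcov_theta <- tryCatch(2 / (n - 1) * solve(H), error = function(e)
    matrix(NA_real_, q, q))
  se <- sqrt(pmax(diag(vcov_theta), 0))

  pt <- model$param_table
  est <- pt$value
  est[pt$free] <- theta
  se_all <- rep(0, nrow(pt))
  se_all[pt$free] <- se

  sds <- sqrt(diag(st$full))          # model-implied SDs, all variables
  std <- est
  for (r in seq_len(nrow(pt))) {
    if (pt$mat[r] == "A") {
      std[r] <- est[r] * sds[pt$j[r]] / sds[pt$i[r]]
    } else if (pt$i[r] != pt$j[r]) {
      std[r] <- est[r] / (sds[pt$i[r]] * sds[pt$j[r]])
    } else {
      std[r] <- est[r] / st$full[pt$i[r], pt$i[r]]  # residual proportion
    }
  }
  scale_fac <- ifelse(est != 0, std / est, 1)
  param <- data.frame(label = pt$label, matrix = pt$mat,
                      lhs = model$vars[pt$i], rhs = model$vars[pt$j],
                      free = pt$free, est = est, se = se_all,
                      ci_lower = est - 1.96 * se_all,
                      ci_upper = est + 1.96 * se_all,
                      std = std, std_se = abs(scale_fac) * se_all,
                      stringsAsFactors = FALSE)
  param$std_ci_lower <- param$std - 1.96 * param$std_se
  param$std_ci_upper <- param$std + 1.96 * param$std_se

  theta_lab <- paste0("theta_", c(spec$indicators, spec$outcomes))
  resid_var <- est[match(theta_lab, pt$label)]
  heywood <- any(resid_var < 0) || est[match("psi", pt$label)] < 0

  fi <- if (df > 0 && df_b > 0) {
    compute_fit_indices(chi_sq, df, chi_b, df_b, n, S = S, Sigma = st$Sigma)
  } else {
    # saturated model: indices undefined except SRMR
    ds <- sqrt(diag(S))
    resid <- (S / (ds %o% ds) - st$Sigma / (ds %o% ds))
    list(cfi = NA_real_, tli = NA_real_, rmsea = NA_real_,
         srmr = sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2)),
         tli_defined = FALSE)
  }

  structure(list(
    spec = spec, model = model, theta = theta, param = param,
    loadings = param[startsWith(param$label, "lambda_"), ],
    paths = param[startsWith(param$label, "beta_"), ],
    psi = est[match("psi", pt$label)],
    residual_variances = stats::setNames(resid_var,
                                         c(spec$indicators, spec$outcomes)),
    S = S, Sigma = st$Sigma, implied_full = st$full, n = n,
    F_ml = fml, chi_sq = chi_sq, df = df,
    chi_sq_baseline = chi_b, df_baseline = df_b,
    fit_indices = fi, q = model$q,
    converged = converged, gradient_norm = gnorm, heywood = heywood,
    vcov = vcov_theta, iterations = opt$iterations
  ), class = "sem_fit")
}

#' Fit the exposome SEM from subject-level data
#'
#' Convenience wrapper: selects the spec's observed variables from a
#' data.frame (listwise-complete rows required; impute upstream), computes
#' the covariance matrix with the n - 1 denominator, and calls
#' [fit_sem_ml()]. The data and means are retained for factor-score
#' extraction.
#'
#' @param data data.frame containing all observed variables of `spec`.
#' @param spec A [sem_spec()].
#' @param ... Passed on to [fit_sem_ml()].
#' @return A `sem_fit` with `data` and `means` attached.
#' @export
sem_mse <- function(data, spec = sem_spec(), ...) {
  model_vars <- c(spec$indicators, spec$outcomes, spec$covariates)
  missing_cols <- setdiff(model_vars, names(data))
  if (length(missing_cols))
    stop_mse(sprintf("data lacks variables: %s",
                     paste(missing_cols, collapse = ", ")), "mse_bad_argument")
  X <- data[, model_vars, drop = FALSE]
  if (anyNA(X))
    stop_mse("listwise-complete data required; impute before fitting",
             "mse_missing_values")
  fit <- fit_sem_ml(stats::cov(X), nrow(X), spec, ...)
  fit$data <- X
  fit$means <- colMeans(X)
  fit
}

#' Incremental and absolute fit indices from chi-square statistics
#'
#' CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0);
#' TLI = ((chi2_b/df_b) - (chi2_m/df_m)) / ((chi2_b/df_b) - 1);
#' RMSEA = sqrt(max(chi2_m - df_m, 0) / (df_m (n - 1)));
#' SRMR = root mean square of the standardized residual covariances over the
#' p(p+1)/2 unique elements (diagonal included). A baseline with
#' chi2_b <= df_b makes the TLI denominator degenerate; TLI is then NA with
#' `tli_defined = FALSE`.
#'
#' @param chi_sq_m,df_m Model chi-square and degrees of freedom.
#' @param chi_sq_b,df_b Baseline (independence) chi-square and df.
#' @param n Sample size.
#' @param S,Sigma Optional sample and model-implied covariance for SRMR.
#' @return List with `cfi`, `tli`, `rmsea`, `srmr`, `tli_defined`.
#' @export
compute_fit_indices <- function(chi_sq_m, df_m, chi_sq_b, df_b, n,
                                S = NULL, Sigma = NULL) {
  if (df_m <= 0 || df_b <= 0)
    stop_mse("degrees of freedom must be positive", "mse_bad_argument")
  num <- max(chi_sq_m - df_m, 0)
  den <- max(chi_sq_b - df_b, chi_sq_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli_defined <- chi_sq_b > df_b
  tli <- if (!tli_defined) NA_real_ else
    ((chi_sq_b / df_b) - (chi_sq_m / df_m)) / ((chi_sq_b / df_b) - 1)
  rmsea <- sqrt(max(chi_sq_m - df_m, 0) / (df_m * (n - 1)))
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    ds <- sqrt(diag(S))
    Rs <- S / (ds %o% ds)
    Ri <- Sigma / (ds %o% ds)
    resid <- (Rs - Ri)[upper.tri(Rs, diag = TRUE)]
    srmr <- sqrt(mean(resid^2))
  }
  list(cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr,
       tli_defined = tli_defined)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> n = %d, chi2(%d) = %.3f, q = %d%s%s\n",
              x$n, x$df, x$chi_sq, x$q,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$heywood) " [Heywood case]" else ""))
  fi <- x$fit_indices
  cat(sprintf("  CFI = %.3f  TLI = %.3f  RMSEA = %.3f  SRMR = %.3f\n",
              fi$cfi, fi$tli, fi$rmsea, fi$srmr))
  invisible(x)
}

#' Summarize a fitted exposome SEM
#'
#' @param object A `sem_fit`.
#' @param ... Unused.
#' @return Invisibly, the parameter table.
#' @export
summary.sem_fit <- function(object, ...) {
  print(object)
  cat("\nStandardized loadings (latent -> indicator):\n")
  l <- object$loadings
  for (r in seq_len(nrow(l)))
    cat(sprintf("  %-22s %6.3f  [%.3f, %.3f]\n", l$lhs[r], l$std[r],
                l$std_ci_lower[r], l$std_ci_upper[r]))
  cat("\nStandardized structural paths (latent -> outcome):\n")
  b <- object$paths
  for (r in seq_len(nrow(b)))
    cat(sprintf("  %-22s %6.3f  [%.3f, %.3f]\n", b$lhs[r], b$std[r],
                b$std_ci_lower[r], b$std_ci_upper[r]))
  invisible(object$param)
}
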
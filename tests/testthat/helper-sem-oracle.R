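# Independent one-factor SEM oracle, deliberately sharing no code with the
# engine: different parameterization (latent variance fixed to 1, all
# loadings free, residual variances on the log scale so positivity is
# structural), different optimizer (optim/BFGS with numerical gradients,
# restarted), and an element-wise covariance construction. Comparisons are
# made on identification-invariant quantities: the ML chi-square and the
# standardized solution.

oracle_fit_onefactor <- function(S, n, vars = colnames(S)) {
  S <- as.matrix(S)[vars, vars]
  p <- length(vars)
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]

  fml <- function(par) {
    l <- par[1:p]
    th <- exp(par[(p + 1):(2 * p)])
    Sig <- tcrossprod(l) + diag(th)
    ld <- determinant(Sig, logarithm = TRUE)
    if (ld$sign <= 0) return(1e9)
    v <- ld$modulus[1] + sum(diag(solve(Sig, S))) - logdetS - p
    if (!is.finite(v)) 1e9 else v
  }

  # crude start: loadings from sqrt of largest off-diagonal structure
  r0 <- stats::cov2cor(S)
  l0 <- sqrt(pmax(0.2, apply(abs(r0 - diag(p)), 1, max))) * sqrt(diag(S))
  par <- c(l0, log(0.5 * diag(S)))
  for (rep in 1:3) {
    o <- stats::optim(par, fml, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
    par <- o$par
  }
  l <- par[1:p]
  th <- exp(par[(p + 1):(2 * p)])
  if (sum(l) < 0) l <- -l      # resolve the global sign indeterminacy
  Sig <- tcrossprod(l) + diag(th)
  list(chi_sq = (n - 1) * o$value,
       std_loadings = stats::setNames(l / sqrt(diag(Sig)), vars),
       F_ml = o$value, loadings = l, theta = th)
}

# Direct arithmetic fit-index oracle (no shared code with the package).
oracle_fit_indices <- function(chi_m, df_m, chi_b, df_b, n) {
  list(cfi = 1 - max(chi_m - df_m, 0) / max(chi_b - df_b, chi_m - df_m, 0),
       rmsea = sqrt(max(chi_m - df_m, 0) / (df_m * (n - 1))),
       tli = ((chi_b / df_b) - (chi_m / df_m)) / ((chi_b / df_b) - 1))
}
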
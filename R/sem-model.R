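# Model definition and covariance-structure machinery for the one-factor
# structural equation model: ten dimension composites load on a latent
# exposome factor which predicts the three clinical outcomes; optional
# exogenous covariates (sensitivity models) predict both the latent and each
# outcome; selected residual covariances may be freed (modification-index
# guided).
#
# Internals use the reticular (RAM) formulation: with variables ordered
# (observed, latent), path matrix A (A[i, j] = coefficient of j in the
# equation for i), symmetric (co)variance matrix S0, and B = (I - A)^-1, the
# model-implied covariance of the observed block is Sigma = M S0 M' with
# M = B[observed, ]. Analytic derivatives of Sigma in each free parameter
# give the gradient of the ML discrepancy and the expected information.

#' Specify the structural equation model
#'
#' @param indicators Indicator (dimension composite) names; default the ten
#'   exposome dimensions.
#' @param fixed_indicator Indicator whose loading is fixed to 1 to identify
#'   the latent scale (default `access_healthcare`).
#' @param outcomes Outcome names regressed on the latent (default the three
#'   clinical outcomes; may be empty for a pure measurement model).
#' @param freed_covariances List of character pairs of observed variables
#'   whose residual covariance is freed.
#' @param covariates Exogenous covariate names; each predicts the latent and
#'   every outcome, with a saturated covariance block among themselves.
#' @return Object of class `sem_spec`.
#' @export
sem_spec <- function(indicators = mse_dimensions(),
                     fixed_indicator = "access_healthcare",
                     outcomes = mse_outcomes(),
                     freed_covariances = list(),
                     covariates = character(0)) {
  if (!fixed_indicator %in% indicators)
    stop_mse("fixed indicator must be among the indicators", "mse_bad_argument")
  obs <- c(indicators, outcomes, covariates)
  if (anyDuplicated(obs))
    stop_mse("indicator/outcome/covariate names must be distinct",
             "mse_bad_argument")
  for (pr in freed_covariances) {
    if (length(pr) != 2L || pr[1] == pr[2] || !all(pr %in% obs))
      stop_mse("freed covariance pairs must be two distinct observed variables",
               "mse_bad_argument")
  }
  structure(list(indicators = indicators, fixed_indicator = fixed_indicator,
                 outcomes = outcomes, freed_covariances = freed_covariances,
                 covariates = covariates),
            class = "sem_spec")
}

# Build the internal model description: variable indices and parameter table.
build_model <- function(spec) {
  obs <- c(spec$indicators, spec$outcomes, spec$covariates)
  vars <- c(obs, ".eta")
  idx <- stats::setNames(seq_along(vars), vars)
  p <- length(obs); t <- length(vars)
  eta <- idx[".eta"]

  pt <- list()
  add <- function(mat, i, j, free, value, label) {
    pt[[length(pt) + 1L]] <<- list(mat = mat, i = i, j = j, free = free,
                                   value = value, label = label)
  }
  for (v in spec$indicators)
    add("A", idx[v], eta, free = v != spec$fixed_indicator,
        value = if (v == spec$fixed_indicator) 1 else NA,
        label = paste0("lambda_", v))
  for (v in spec$outcomes)
    add("A", idx[v], eta, TRUE, NA, paste0("beta_", v))
  for (cv in spec$covariates) {
    add("A", eta, idx[cv], TRUE, NA, paste0("gamma_eta_", cv))
    for (v in spec$outcomes)
      add("A", idx[v], idx[cv], TRUE, NA, paste0("gamma_", v, "_", cv))
  }
  add("S", eta, eta, TRUE, NA, "psi")
  for (v in c(spec$indicators, spec$outcomes))
    add("S", idx[v], idx[v], TRUE, NA, paste0("theta_", v))
  nc <- length(spec$covariates)
  if (nc) {
    for (a in seq_len(nc)) for (b in a:nc)
      add("S", idx[spec$covariates[a]], idx[spec$covariates[b]], TRUE, NA,
          paste0("phi_", spec$covariates[a], "_", spec$covariates[b]))
  }
  for (pr in spec$freed_covariances)
    add("S", idx[pr[1]], idx[pr[2]], TRUE, NA,
        paste0("cov_", pr[1], "_", pr[2]))

  pt <- do.call(rbind, lapply(pt, function(x)
    data.frame(mat = x$mat, i = x$i, j = x$j, free = x$free, value = x$value,
               label = x$label, stringsAsFactors = FALSE)))
  list(spec = spec, vars = vars, obs = obs, idx = idx, p = p, t = t,
       eta = eta, param_table = pt, q = sum(pt$free))
}

# Fill A and S0 from the parameter table and a free-parameter vector.
model_matrices <- function(model, theta) {
  A <- matrix(0, model$t, model$t)
  S0 <- matrix(0, model$t, model$t)
  pt <- model$param_table
  vals <- pt$value
  vals[pt$free] <- theta
  for (r in seq_len(nrow(pt))) {
    if (pt$mat[r] == "A") {
      A[pt$i[r], pt$j[r]] <- vals[r]
    } else {
      S0[pt$i[r], pt$j[r]] <- vals[r]
      S0[pt$j[r], pt$i[r]] <- vals[r]
    }
  }
  list(A = A, S0 = S0)
}

# Model-implied covariance (observed block) plus reusable intermediates.
sigma_of_theta <- function(model, theta) {
  mm <- model_matrices(model, theta)
  B <- solve(diag(model$t) - mm$A)
  M <- B[seq_len(model$p), , drop = FALSE]
  full <- B %*% mm$S0 %*% t(B)              # covariance of all variables
  list(Sigma = full[seq_len(model$p), seq_len(model$p), drop = FALSE],
       full = full, B = B, M = M, S0 = mm$S0, A = mm$A)
}

# List of dSigma/dtheta_q (p x p matrices) for free parameters; if `extra`
# rows (same format as param_table) are supplied their derivatives are
# appended (used by modification indices).
sigma_derivatives <- function(model, st, extra = NULL) {
  pt <- model$param_table[model$param_table$free, , drop = FALSE]
  if (!is.null(extra)) pt <- rbind(pt, extra)
  M <- st$M; B <- st$B; S0 <- st$S0
  lapply(seq_len(nrow(pt)), function(r) {
    i <- pt$i[r]; j <- pt$j[r]
    if (pt$mat[r] == "S") {
      D <- M[, i] %o% M[, j]
      if (i != j) D <- D + t(D)
      D
    } else {
      w <- as.numeric(M %*% S0 %*% B[j, ])
      M[, i] %o% w + w %o% M[, i]
    }
  })
}

fml_value <- function(S, Sigma, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet <- 2 * sum(log(diag(ch)))
  logdet + sum(diag(chol2inv(ch) %*% S)) - logdetS - nrow(S)
}
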
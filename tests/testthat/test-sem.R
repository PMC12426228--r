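# SEM engine: discrepancy minimization, identification invariance,
# standardization, factor scores, modification indices, bootstrap.

test_that("a saturated model attains F_ML = 0 and a just-identified Heywood
           structure is flagged", {
  # 3 observed variables, one factor: q = 6 = p(p+1)/2, F = 0
  spec3 <- sem_spec(indicators = c("a", "b", "c"), fixed_indicator = "a",
                    outcomes = character(0))
  set.seed(2)
  z <- rnorm(300)
  d <- data.frame(a = 0.8 * z + rnorm(300, 0, .5),
                  b = 0.7 * z + rnorm(300, 0, .6),
                  c = 0.6 * z + rnorm(300, 0, .7))
  fit <- fit_sem_ml(cov(d), 300, spec3)
  expect_lt(abs(fit$F_ml), 1e-8)
  expect_lt(abs(fit$chi_sq), 1e-5)
  expect_equal(fit$df, 0)
  expect_false(fit$heywood)

  # Heywood correlation structure: lambda1^2 = .8*.8/.3 = 2.13 > 1 (the
  # matrix itself is positive definite)
  R <- rbind(c(1, .8, .8), c(.8, 1, .3), c(.8, .3, 1))
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  fith <- fit_sem_ml(R, 200, spec3)
  expect_true(fith$heywood)
  expect_true(any(fith$residual_variances < 0))
})

test_that("chi-square is invariant to the choice of fixed indicator", {
  d <- analysis_table(600, seed = 31)
  S <- cov(d)
  f1 <- fit_sem_ml(S, 600, sem_spec(fixed_indicator = "access_healthcare"))
  f2 <- fit_sem_ml(S, 600, sem_spec(fixed_indicator = "education"))
  f3 <- fit_sem_ml(S, 600, sem_spec(fixed_indicator = "relations"))
  expect_lt(abs(f1$chi_sq - f2$chi_sq), 1e-4)
  expect_lt(abs(f1$chi_sq - f3$chi_sq), 1e-4)
  # standardized solutions agree too
  expect_equal(setNames(f1$loadings$std, f1$loadings$lhs),
               setNames(f2$loadings$std, f2$loadings$lhs), tolerance = 1e-5)
})

test_that("standardized loadings are equivariant under indicator rescaling", {
  d <- analysis_table(800, seed = 32)
  f1 <- sem_mse(d)
  d2 <- d
  d2$education <- d$education * 2        # change of units
  f2 <- sem_mse(d2)
  expect_equal(setNames(f1$loadings$std, f1$loadings$lhs),
               setNames(f2$loadings$std, f2$loadings$lhs), tolerance = 1e-4)
  # the unstandardized loading absorbs the scale change instead
  l1 <- f1$loadings$est[f1$loadings$lhs == "education"]
  l2 <- f2$loadings$est[f2$loadings$lhs == "education"]
  expect_equal(l2 / l1, 2, tolerance = 1e-3)
})

test_that("fit indices reproduce their closed forms exactly", {
  fi <- compute_fit_indices(100, 60, 1000, 78, 1001)
  expect_equal(fi$cfi, 1 - 40 / 922)
  expect_equal(fi$rmsea, sqrt(40 / 60000))
  expect_equal(fi$tli, ((1000 / 78) - (100 / 60)) / ((1000 / 78) - 1))
  # chi2 = df -> CFI 1, RMSEA 0
  fi0 <- compute_fit_indices(60, 60, 1000, 78, 1001)
  expect_equal(fi0$cfi, 1)
  expect_equal(fi0$rmsea, 0)
  # Sigma = S -> SRMR 0
  S <- diag(3) + 0.3
  fi1 <- compute_fit_indices(60, 60, 1000, 78, 1001, S = S, Sigma = S)
  expect_equal(fi1$srmr, 0)
  # degenerate baseline
  fid <- compute_fit_indices(10, 5, 4, 6, 100)
  expect_false(fid$tli_defined)
  expect_true(is.na(fid$tli))
})

test_that("factor scores recover the latent and are invariant to affine
           indicator rescaling", {
  d <- analysis_table(2000, seed = 33)
  fit <- sem_mse(d)
  sc <- extract_factor_scores(fit)
  expect_gt(cor(sc$score, attr(d, "latent")), 0.9)
  scb <- extract_factor_scores(fit, method = "bartlett")
  expect_gt(cor(sc$score, scb$score), 0.99)
  # affine rescale of all indicators: scores unchanged up to affine map
  d2 <- d
  for (v in mse_dimensions()) d2[[v]] <- 3 + 2 * d[[v]]
  sc2 <- extract_factor_scores(sem_mse(d2))
  expect_gt(abs(cor(sc$score, sc2$score)), 1 - 1e-6)

  # single indicator, loading 1, zero residual: score = centered indicator
  spec1 <- sem_spec(indicators = c("x", "y", "z"), fixed_indicator = "x",
                    outcomes = character(0))
  set.seed(4)
  eta <- rnorm(500)
  d1 <- data.frame(x = eta, y = eta + rnorm(500, 0, .5),
                   z = 0.5 * eta + rnorm(500, 0, .8))
  f1 <- sem_mse(d1, spec1)
  s1 <- extract_factor_scores(f1)
  expect_gt(cor(s1$score, eta - mean(eta)), 0.999)
})

test_that("modification indices are null-calibrated and detect an omitted
           residual covariance", {
  # null: the fitted model is the generating model
  n_rep <- 10
  below <- total <- 0
  for (r in seq_len(n_rep)) {
    d <- analysis_table(1000, seed = 300 + r)
    fit <- sem_mse(d)
    mi <- modification_indices(fit, within = "indicators")$mi
    below <- below + sum(mi < 3.84)
    total <- total + length(mi)
  }
  expect_gt(below / total, 0.9)

  # detection: correlated residuals between education and assets omitted
  hits <- 0
  for (r in seq_len(10)) {
    d <- analysis_table(2000, seed = 400 + r)
    extra <- rnorm(2000, 0, 0.45)
    d$education <- d$education + extra
    d$assets <- d$assets + extra
    fit <- sem_mse(d)
    top <- modification_indices(fit, within = "indicators")[1, ]
    hits <- hits + (setequal(c(top$var1, top$var2), c("education", "assets")))
    # freeing the top pair really drops chi-square
    if (r == 1) {
      fit2 <- sem_mse(d, sem_spec(freed_covariances =
                                    list(c("education", "assets"))))
      expect_gt(fit$chi_sq - fit2$chi_sq, 0)
      # MI approximates the realized drop
      mi <- modification_index(fit, c("education", "assets"))
      expect_lt(abs(mi - (fit$chi_sq - fit2$chi_sq)) /
                  (fit$chi_sq - fit2$chi_sq), 0.25)
    }
  }
  expect_gte(hits, 9)
  d <- analysis_table(500, seed = 2)
  fit <- sem_mse(d, sem_spec(freed_covariances = list(c("education", "assets"))))
  expect_error(modification_index(fit, c("education", "assets")),
               class = "mse_already_free")
})

test_that("exogenous covariates enter the structural model", {
  set.seed(8)
  n <- 1500
  age <- rnorm(n)
  eta <- 0.4 * age + rnorm(n)
  d <- as.data.frame(lapply(msexposome:::default_loadings(), function(l)
    l * eta + rnorm(n, 0, sqrt(1 - l^2))))
  names(d) <- mse_dimensions()
  d$cognition <- 0.3 * eta + 0.2 * age + rnorm(n, 0, .9)
  d$functional_ability <- 0.1 * eta + rnorm(n)
  d$neuropsychiatric <- 0.1 * eta + rnorm(n)
  d$age <- age
  fit <- sem_mse(d, sem_spec(covariates = "age"))
  expect_true(fit$converged)
  # the latent is identified on the fixed indicator's scale
  # (access_healthcare, generating loading 0.506), so unstandardized
  # coefficients shrink by that factor
  lam_fix <- msexposome:::default_loadings()["access_healthcare"]
  g <- fit$param[fit$param$label == "gamma_eta_age", ]
  expect_lt(abs(g$est - 0.4 * lam_fix), 0.1)
  gc <- fit$param[fit$param$label == "gamma_cognition_age", ]
  expect_lt(abs(gc$est - 0.2), 0.1)
})

test_that("bootstrap paths are reproducible, consistent with the full-sample
           fit, and converge their CI onto a null path", {
  d <- analysis_table(700, seed = 41)
  b1 <- bootstrap_sem(d, B = 8, seed = 9)
  b2 <- bootstrap_sem(d, B = 8, seed = 9)
  expect_identical(b1$paths, b2$paths)

  b <- bootstrap_sem(d, B = 60, seed = 10)
  full <- sem_mse(d)
  full_paths <- setNames(full$paths$std, full$paths$lhs)
  expect_lt(max(abs(colMeans(b$paths) - full_paths[colnames(b$paths)])), 0.03)

  # null generating model: percentile CI straddles 0 for most repeats
  dn <- analysis_table(600, paths = c(cognition = 0, functional_ability = 0,
                                      neuropsychiatric = 0), seed = 42)
  bn <- bootstrap_sem(dn, B = 40, seed = 11)
  expect_true(bn$ci[1, "cognition"] <= 0 && bn$ci[2, "cognition"] >= 0)
})
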
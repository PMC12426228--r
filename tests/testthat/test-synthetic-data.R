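# Synthetic cohort, missingness, connectome and motion-trace generators.

test_that("generators are deterministic under identical spec + seed", {
  s <- small_cohort_spec(seed = 5)
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1$items, c2$items)
  expect_identical(c1$outcomes, c2$outcomes)
  c3 <- generate_cohort(small_cohort_spec(seed = 6))
  expect_false(identical(c1$items, c3$items))
})

test_that("noise-free continuous items are perfectly correlated with the
           latent and attenuation follows the closed form", {
  # noise-free limit, loading 1, continuous items
  s0 <- cohort_spec(n_per_group = c(HC = 100, AD = 50, FTLD = 50),
                    item_counts = setNames(c(3, rep(1, 9)), mse_dimensions()),
                    loading_by_dimension = setNames(rep(1, 10), mse_dimensions()),
                    item_noise_sd = 0, item_families = "continuous", seed = 2)
  ch0 <- generate_cohort(s0)
  expect_equal(abs(cor(ch0$items[[1]], ch0$latent)), 1, tolerance = 1e-12)

  # closed-form attenuation: cor = l / sqrt(l^2 + sd^2) for loading l
  lam <- 0.7; nsd <- 0.6
  s1 <- cohort_spec(n_per_group = c(HC = 1000, AD = 500, FTLD = 500),
                    item_counts = setNames(c(4, rep(1, 9)), mse_dimensions()),
                    loading_by_dimension = setNames(rep(lam, 10), mse_dimensions()),
                    latent_mean_by_group = c(HC = 0, AD = 0, FTLD = 0),
                    item_noise_sd = nsd, item_families = "continuous", seed = 3)
  ch1 <- generate_cohort(s1)
  target <- lam / sqrt(lam^2 + nsd^2)
  r <- abs(cor(ch1$items[["education_01"]], ch1$latent))
  expect_lt(abs(r - target), 0.05)
})

test_that("averaging noise-free items recovers the latent ordering", {
  s <- cohort_spec(n_per_group = c(HC = 150, AD = 100, FTLD = 50),
                   item_counts = setNames(rep(3, 10), mse_dimensions()),
                   loading_by_dimension = setNames(rep(0.8, 10), mse_dimensions()),
                   item_noise_sd = 0, item_families = "continuous", seed = 4)
  ch <- generate_cohort(s)
  sc <- compute_dimension_scores(ch$items, ch$meta)
  global <- rowMeans(sc[, -1])
  expect_gt(cor(global, ch$latent), 0.99)
})

test_that("generated demographics match the spec's moments", {
  s <- cohort_spec(n_per_group = c(HC = 5000, AD = 5000, FTLD = 5000),
                   item_counts = setNames(rep(1, 10), mse_dimensions()),
                   seed = 10)
  ch <- generate_cohort(s)
  for (g in c("HC", "AD", "FTLD")) {
    rows <- ch$demographics$group == g
    ms <- s$age_mean_sd_by_group[[g]]
    se <- ms[2] / sqrt(sum(rows))
    expect_lt(abs(mean(ch$demographics$age[rows]) - ms[1]), 2 * se)
  }
})

test_that("group outcome locations and the HC functional floor emerge", {
  ch <- generate_cohort(small_cohort_spec(n = c(HC = 400, AD = 300, FTLD = 150),
                                          total_items = 10, seed = 12))
  d <- ch$demographics
  expect_gt(mean(ch$outcomes$cognition[d$group == "HC"]), 25)
  expect_lt(mean(ch$outcomes$cognition[d$group == "AD"]), 23)
  hc_fa <- ch$outcomes$functional_ability[d$group == "HC"]
  expect_gt(mean(hc_fa == 0), 0.3)       # truncation-induced floor
  expect_true(all(ch$outcomes$neuropsychiatric >= 0 &
                    ch$outcomes$neuropsychiatric <= 36))
})

test_that("missingness hits its target rate and MAR reduces to MCAR at
           slope zero", {
  ch <- generate_cohort(small_cohort_spec(n = c(HC = 900, AD = 700, FTLD = 400),
                                          total_items = 20, seed = 6))
  holed <- apply_missingness(ch$items, missingness_spec(0.197), seed = 3)
  rate <- mean(is.na(as.matrix(holed)))
  expect_true(rate >= 0.187 && rate <= 0.207)

  expect_identical(apply_missingness(ch$items, missingness_spec(0)), ch$items)

  age <- ch$demographics$age
  m0 <- apply_missingness(ch$items, missingness_spec(0.2, "MAR-on-age",
                                                     age_slope = 0),
                          age = age, seed = 4)
  J <- ncol(m0)
  ind <- rowSums(is.na(as.matrix(m0)))
  f <- summary(glm(cbind(ind, J - ind) ~ age, family = binomial))
  expect_gt(f$coefficients["age", "Pr(>|z|)"], 0.01)   # no age signal

  m1 <- apply_missingness(ch$items, missingness_spec(0.2, "MAR-on-age",
                                                     age_slope = 1.5),
                          age = age, seed = 4)
  ind1 <- rowMeans(is.na(as.matrix(m1)))
  expect_gt(cor(ind1, age), 0.3)                        # age-driven
  expect_error(missingness_spec(0.5), class = "mse_bad_argument")
})

test_that("connectomes are symmetric, zero-diagonal, with the requested
           edge effects", {
  n <- 60
  expo <- rnorm(n)
  sp <- connectome_spec(8, effect_edges = data.frame(i = 2, j = 5, slope = 1),
                        noise_sd = 0)
  cs <- generate_connectomes(sp, expo, seed = 2)
  for (s in 1:5) {
    expect_equal(cs$matrices[[s]], t(cs$matrices[[s]]))
    expect_equal(diag(cs$matrices[[s]]), rep(0, 8))
  }
  edge <- vapply(cs$matrices, function(m) m[2, 5], 1)
  expect_equal(edge, expo, tolerance = 1e-12)   # noise-free limit

  # OLS recovers a 0.5 slope within sampling error at n = 500
  expo2 <- rnorm(500)
  sp2 <- connectome_spec(6, effect_edges = data.frame(i = 1, j = 4, slope = 0.5),
                         noise_sd = 1)
  cs2 <- generate_connectomes(sp2, expo2, seed = 9)
  e2 <- vapply(cs2$matrices, function(m) m[1, 4], 1)
  expect_lt(abs(coef(lm(e2 ~ expo2))[2] - 0.5), 0.15)

  expect_error(connectome_spec(6, data.frame(i = 2, j = 2, slope = 1)),
               class = "mse_bad_argument")
  expect_error(connectome_spec(6, data.frame(i = c(1, 2), j = c(2, 1),
                                             slope = 1)),
               class = "mse_duplicate_edge")
})

test_that("motion traces spike exactly where requested", {
  tr <- generate_motion_trace(100, spike_frames = c(10, 50), spike_amplitude = 0.5,
                              seed = 3)
  expect_identical(which(tr$fd > 0.2), c(10L, 50L))
  clean <- generate_motion_trace(100, seed = 3)
  expect_identical(sum(clean$fd > 0.2), 0L)
  sub <- generate_motion_trace(100, spike_frames = 1:30, spike_amplitude = 0.19,
                               seed = 3)
  expect_identical(sum(sub$fd > 0.2), 0L)
  expect_error(generate_motion_trace(100, spike_frames = 101),
               class = "mse_bad_argument")
})
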
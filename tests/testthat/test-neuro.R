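# Connectivity associations, per-ROI FDR, degree centrality, QC metrics.

test_that("Fisher z round-trips and matches its closed form", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), class = "mse_bad_argument")
})

test_that("edge association is calibrated on null edges and detects an
           injected slope", {
  set.seed(23)
  n <- 500
  expo <- rnorm(n)
  sp <- connectome_spec(40, effect_edges = data.frame(i = 1, j = 5, slope = 0.6),
                        noise_sd = 1)
  cs <- generate_connectomes(sp, expo, seed = 24)
  es <- edge_association(cs, expo)
  # null edges: about 5% of p-values below 0.05
  ut <- upper.tri(es$p)
  ut[1, 5] <- FALSE
  null_p <- es$p[ut]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.02)
  expect_lt(es$p[1, 5], 1e-6)
  expect_gt(es$t[1, 5], 0)
})

test_that("covariate adjustment absorbs an age-confounded edge", {
  hits <- 0
  for (r in 1:20) {
    set.seed(600 + r)
    n <- 300
    age <- rnorm(n)
    expo <- 0.7 * age + rnorm(n, 0, sqrt(1 - 0.49))   # exposure tracks age
    sp <- connectome_spec(6, effect_edges = data.frame(i = 2, j = 4, slope = 0),
                          covariate_edges = data.frame(i = 2, j = 4,
                                                       covariate = "age",
                                                       slope = 0.5))
    cs <- generate_connectomes(sp, expo, covariates = data.frame(age = age),
                               seed = 600 + r)
    # unadjusted: the edge looks exposure-related
    es_raw <- edge_association(cs, expo, covariates = NULL)
    # adjusted for age: attenuated to null
    es_adj <- edge_association(cs, expo, covariates = data.frame(age = age))
    hits <- hits + (abs(es_adj$t[2, 4]) < 2)
    if (r == 1) expect_gt(abs(es_raw$t[2, 4]), 2)
  }
  expect_gte(hits, 17)
})

test_that("row-wise BH decisions match the reference step-up oracle and are
           monotone in q", {
  set.seed(25)
  p <- 12
  P <- matrix(runif(p * p), p, p)
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  diag(P) <- NA
  stats <- structure(list(p = P, t = P, df = 100), class = "edge_stats")
  mask <- row_fdr_mask(stats, q = 0.05, symmetrize = FALSE)
  for (i in seq_len(p)) {
    idx <- setdiff(seq_len(p), i)
    expect_identical(unname(mask[i, idx]),
                     p.adjust(P[i, idx], "BH") <= 0.05)
  }
  m1 <- row_fdr_mask(stats, q = 0.01)
  m5 <- row_fdr_mask(stats, q = 0.05)
  expect_true(all(m5[m1]))          # q=0.01 mask nested in q=0.05 mask

  # all p = 1 -> empty; one tiny p in a row -> significant
  P1 <- matrix(1, p, p); diag(P1) <- NA
  P1[1, 2] <- P1[2, 1] <- 1e-9
  s1 <- structure(list(p = P1, t = P1), class = "edge_stats")
  expect_true(row_fdr_mask(s1)[1, 2])
  expect_equal(sum(row_fdr_mask(s1)), 2)
})

test_that("degree centrality equals brute-force incident-edge enumeration", {
  set.seed(26)
  p <- 15
  mask <- matrix(runif(p * p) < 0.2, p, p)
  mask[lower.tri(mask)] <- t(mask)[lower.tri(mask)]
  diag(mask) <- FALSE
  tmat <- matrix(rnorm(p * p), p, p)
  tmat[lower.tri(tmat)] <- t(tmat)[lower.tri(tmat)]
  dc <- degree_centrality(mask, tmat)
  brute <- sapply(seq_len(p), function(i)
    sum(vapply(seq_len(p), function(j) j != i && mask[i, j], TRUE)))
  expect_identical(dc$degree, as.integer(brute))
  expect_identical(dc$degree, dc$degree_pos + dc$degree_neg)
  # handshake identity
  expect_identical(sum(dc$degree), as.integer(2 * sum(mask[upper.tri(mask)])))

  # star mask
  star <- matrix(FALSE, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- TRUE
  ds <- degree_centrality(star)
  expect_identical(ds$degree, c(5L, rep(1L, 5)))
  expect_identical(degree_centrality(matrix(FALSE, 4, 4))$degree, rep(0L, 4))
  bad <- mask; bad[1, 2] <- !bad[1, 2]
  expect_error(degree_centrality(bad), class = "mse_asymmetric")
})

test_that("scrubbing respects the 70% retention boundary and QC formulas", {
  t30 <- generate_motion_trace(100, spike_frames = 1:30, spike_amplitude = 0.5)
  q30 <- scrub_and_qc(t30)
  expect_equal(q30$artifact_free_proportion, 0.70)
  expect_false(q30$excluded)                 # boundary inclusive
  t31 <- generate_motion_trace(100, spike_frames = 1:31, spike_amplitude = 0.5)
  expect_true(scrub_and_qc(t31)$excluded)
  clean <- scrub_and_qc(generate_motion_trace(100))
  expect_equal(clean$artifact_free_proportion, 1.0)
  # global-signal flagging unions with FD flagging
  gs <- rnorm(100); gs[7] <- 50
  qg <- scrub_and_qc(generate_motion_trace(100), global_signal = gs,
                     gs_z_threshold = 5)
  expect_true(qg$flagged[7])
})

test_that("signal quality follows mean/sd definitions and flags degenerate
           segments", {
  x <- rep(c(90, 110), 10)            # mean 100, sd ~10.26
  sq <- signal_quality(x, segment_len = 20)
  expect_equal(sq$tsnr[1], mean(x) / sd(x))
  set.seed(27)
  y <- rnorm(20000, 100, 10)
  sqy <- signal_quality(y, segment_len = 20)
  expect_lt(abs(median(sqy$tsnr) - 10), 0.5)   # concentrates near mu/sigma
  sqc <- signal_quality(rep(5, 40), segment_len = 20)
  expect_true(all(sqc$undefined_segments))
  expect_true(all(is.na(sqc$tsnr)))
})
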
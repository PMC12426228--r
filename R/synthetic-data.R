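# Seeded synthetic cohorts with the latent structure the analysis assumes:
# one latent adversity factor loading on ten bounded dimension composites,
# three clinical outcomes regressed on the latent, diagnostic groups with
# distinct outcome locations (including the healthy-control floor on
# functional ability), configurable missingness, connectomes whose edges
# depend linearly on the exposure score, and motion traces for QC fixtures.
# Raw study data are under restricted access; these generators make every
# downstream stage testable without any download.

default_item_counts <- function(total = 319) {
  # Split of the default 319-item instrument across dimensions; proportions
  # chosen once to reflect questionnaire breadth (traumatic events largest:
  # many yes/no items per life period and perpetrator).
  base <- c(education = 18, food_insecurity = 6, financial_status = 30,
            assets = 60, access_healthcare = 27, childhood_labor = 8,
            subjective_ses = 3, childhood_experiences = 30,
            traumatic_events = 105, relations = 32)
  if (total == 319) return(base)
  out <- pmax(1, round(base * total / 319))
  names(out) <- names(base)
  out
}

default_loadings <- function() {
  # Standardized loading targets; the five large ones follow published
  # whole-sample estimates, the remainder fixed once in (0.1, 0.5].
  c(education = 0.732, food_insecurity = 0.702, financial_status = 0.694,
    assets = 0.649, access_healthcare = 0.506, childhood_labor = 0.45,
    subjective_ses = 0.45, childhood_experiences = 0.40,
    traumatic_events = 0.17, relations = 0.12)
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group Named integer vector (HC, AD, FTLD), each >= 2.
#' @param latent_mean_by_group Mean of the latent exposome factor per group
#'   (higher = less adversity); unit within-group variance.
#' @param item_counts Named integers, items per dimension (default totals 319).
#' @param loading_by_dimension Standardized dimension loadings in (0, 1].
#' @param item_noise_sd Item-level noise SD (> 0 unless exactly 0 for the
#'   noise-free limit).
#' @param item_families Cycled over items within each dimension:
#'   subset of `"continuous"`, `"likert"`, `"binary"`, `"count"`.
#' @param age_mean_sd_by_group List of c(mean, sd) per group.
#' @param sex_prob_by_group Probability of female per group, in [0, 1].
#' @param seed Integer seed fanned out into per-stage substreams.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 1175, AD = 781, FTLD = 255),
                        latent_mean_by_group = c(HC = 0, AD = -0.2, FTLD = -0.2),
                        item_counts = default_item_counts(),
                        loading_by_dimension = default_loadings(),
                        item_noise_sd = 0.6,
                        item_families = c("continuous", "likert", "binary"),
                        age_mean_sd_by_group = list(HC = c(60.21, 11.62),
                                                    AD = c(70.5, 8.4),
                                                    FTLD = c(67.02, 7.78)),
                        sex_prob_by_group = c(HC = 0.730, AD = 0.633, FTLD = 0.510),
                        seed = 1) {
  for (n in n_per_group) check_number(n, "n_per_group", lower = 2, integer = TRUE)
  if (any(loading_by_dimension <= 0 | loading_by_dimension > 1))
    stop_mse("loadings must lie in (0, 1]", "mse_bad_argument")
  check_number(item_noise_sd, "item_noise_sd", lower = 0)
  if (any(sex_prob_by_group < 0 | sex_prob_by_group > 1))
    stop_mse("sex probabilities must lie in [0, 1]", "mse_bad_argument")
  stopifnot(setequal(names(item_counts), mse_dimensions()),
            setequal(names(loading_by_dimension), mse_dimensions()))
  structure(list(n_per_group = n_per_group,
                 latent_mean_by_group = latent_mean_by_group,
                 item_counts = item_counts,
                 loading_by_dimension = loading_by_dimension,
                 item_noise_sd = item_noise_sd,
                 item_families = match.arg(item_families,
                                           c("continuous", "likert", "binary",
                                             "count"), several.ok = TRUE),
                 age_mean_sd_by_group = age_mean_sd_by_group,
                 sex_prob_by_group = sex_prob_by_group,
                 seed = seed),
            class = "cohort_spec")
}

#' Specification of latent-to-outcome structural paths
#'
#' Defaults are the whole-sample standardized paths toward cognition,
#' functional ability and neuropsychiatric symptoms, with group-specific
#' instrument locations/scales matching the cohort characterization table.
#' Outcomes are generated on the raw instrument scale (functional ability and
#' neuropsychiatric symptoms increase with impairment; inversion happens in
#' the scoring pipeline) and truncated to the instrument bounds, which
#' reproduces the healthy-control floor on functional ability.
#'
#' @param path_by_outcome Standardized paths, |beta| < 1.
#' @param residual_sd_by_outcome Residual SDs on the standardized scale;
#'   default sqrt(1 - beta^2) so standardized outcomes have unit variance.
#' @param scale_by_group List per outcome of a 3x2 matrix (rows HC/AD/FTLD,
#'   columns mean/sd) on the instrument scale.
#' @param instrument_max Upper bounds (MMSE 30, PFAQ 30, NPI-Q 36).
#' @return Object of class `outcome_path_spec`.
#' @export
outcome_path_spec <- function(
    path_by_outcome = c(cognition = 0.261, functional_ability = 0.079,
                        neuropsychiatric = 0.105),
    residual_sd_by_outcome = sqrt(1 - path_by_outcome^2),
    scale_by_group = list(
      cognition = rbind(HC = c(27.50, 2.90), AD = c(20.93, 4.41),
                        FTLD = c(21.25, 6.05)),
      functional_ability = rbind(HC = c(0.20, 1.11), AD = c(12.16, 8.11),
                                 FTLD = c(13.69, 9.14)),
      neuropsychiatric = rbind(HC = c(1.45, 2.90), AD = c(6.57, 5.71),
                               FTLD = c(10.48, 7.02))),
    instrument_max = c(cognition = 30, functional_ability = 30,
                       neuropsychiatric = 36)) {
  if (any(abs(path_by_outcome) >= 1))
    stop_mse("standardized paths must satisfy |beta| < 1", "mse_bad_argument")
  if (any(residual_sd_by_outcome <= 0))
    stop_mse("residual SDs must be positive", "mse_bad_argument")
  structure(list(path_by_outcome = path_by_outcome,
                 residual_sd_by_outcome = residual_sd_by_outcome,
                 scale_by_group = scale_by_group,
                 instrument_max = instrument_max),
            class = "outcome_path_spec")
}

item_native_value <- function(u, family) {
  # Monotone map from the latent+noise score to a native response scale.
  switch(family,
         continuous = 10 + 4 * u,
         likert = pmin(4, pmax(0, floor(2.5 + 1.2 * u))),
         binary = as.numeric(u > 0),
         count = pmax(0, round(3 + 2 * u)))
}

#' Generate a synthetic cohort
#'
#' Item j of dimension d is `loading_d * latent + noise`, pushed through a
#' monotone map onto its native bounded scale; items alternate polarity
#' (even-indexed items are generated from the negated signal and flagged
#' `adversity_high`). Outcomes are `path * latent + residual` on the
#' standardized scale, mapped to instrument units per group and truncated to
#' the instrument bounds. Identical spec + seed gives identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param paths An [outcome_path_spec()].
#' @return Object of class `synthetic_cohort`: `items` (raw responses),
#'   `meta` ([item_meta()]), `outcomes` (raw instrument values),
#'   `demographics` (group, age, sex), `latent` (true factor scores).
#' @export
generate_cohort <- function(spec, paths = outcome_path_spec()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(paths, "outcome_path_spec"))
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)

  latent <- with_seed(substream_seed(spec$seed, "latent"), {
    stats::rnorm(n, mean = spec$latent_mean_by_group[groups], sd = 1)
  })

  demo <- with_seed(substream_seed(spec$seed, "demographics"), {
    age <- vapply(seq_len(n), function(i) {
      ms <- spec$age_mean_sd_by_group[[groups[i]]]
      stats::rnorm(1, ms[1], ms[2])
    }, 1)
    sex <- stats::rbinom(n, 1, spec$sex_prob_by_group[groups])
    data.frame(subject_id = sprintf("s%04d", seq_len(n)), group = groups,
               age = age, sex = ifelse(sex == 1, "F", "M"),
               stringsAsFactors = FALSE)
  })

  items <- with_seed(substream_seed(spec$seed, "items"), {
    cols <- list()
    ids <- dims <- pols <- character(0)
    for (d in mse_dimensions()) {
      lam <- spec$loading_by_dimension[d]
      for (j in seq_len(spec$item_counts[d])) {
        id <- sprintf("%s_%02d", d, j)
        fam <- spec$item_families[(j - 1) %% length(spec$item_families) + 1]
        pol <- if (j %% 2 == 0) "adversity_high" else "adversity_low"
        u <- lam * latent + stats::rnorm(n, 0, spec$item_noise_sd)
        if (pol == "adversity_high") u <- -u
        cols[[id]] <- item_native_value(u, fam)
        ids <- c(ids, id); dims <- c(dims, d); pols <- c(pols, pol)
      }
    }
    list(tab = as.data.frame(cols), meta = item_meta(ids, dims, pols))
  })

  outcomes <- with_seed(substream_seed(spec$seed, "outcomes"), {
    out <- data.frame(subject_id = demo$subject_id, stringsAsFactors = FALSE)
    for (k in mse_outcomes()) {
      beta <- paths$path_by_outcome[k]
      std <- beta * latent + stats::rnorm(n, 0, paths$residual_sd_by_outcome[k])
      sc <- paths$scale_by_group[[k]]
      raw <- numeric(n)
      for (g in rownames(sc)) {
        rows <- groups == g
        # higher latent = less adversity = better outcome; raw functional /
        # neuropsychiatric scales increase with impairment, hence the flip
        dir <- if (k == "cognition") 1 else -1
        raw[rows] <- sc[g, 1] + sc[g, 2] * dir * std[rows]
      }
      out[[k]] <- pmin(paths$instrument_max[k], pmax(0, raw))
    }
    out
  })

  structure(list(items = items$tab, meta = items$meta, outcomes = outcomes,
                 demographics = demo, latent = latent, spec = spec,
                 paths = paths),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d items, 3 outcomes\n",
              nrow(x$items),
              paste(sprintf("%s=%d", names(x$spec$n_per_group),
                            x$spec$n_per_group), collapse = ", "),
              ncol(x$items)))
  invisible(x)
}

#' Missingness specification
#'
#' @param overall_rate Target per-cell missing rate, in [0, 0.5).
#' @param mechanism `"MCAR"` or `"MAR-on-age"` (missingness probability a
#'   logistic function of age; the intercept is calibrated so the realized
#'   overall rate matches `overall_rate`).
#' @param age_slope Log-odds slope per SD of age under MAR (default 1).
#' @return Object of class `missingness_spec`.
#' @export
missingness_spec <- function(overall_rate, mechanism = c("MCAR", "MAR-on-age"),
                             age_slope = 1) {
  check_number(overall_rate, "overall_rate", lower = 0, upper = 0.5 - 1e-12)
  structure(list(overall_rate = overall_rate, mechanism = match.arg(mechanism),
                 age_slope = age_slope),
            class = "missingness_spec")
}

#' Inject missing values into an item table
#'
#' @param table data.frame of item responses.
#' @param m A [missingness_spec()].
#' @param age Per-subject age, required for `"MAR-on-age"`.
#' @param seed Integer seed.
#' @return The table with NAs injected.
#' @export
apply_missingness <- function(table, m, age = NULL, seed = 1) {
  stopifnot(inherits(m, "missingness_spec"))
  if (m$overall_rate == 0) return(table)
  tab <- as.data.frame(table)
  n <- nrow(tab); J <- ncol(tab)
  prob <- if (m$mechanism == "MCAR") {
    rep(m$overall_rate, n)
  } else {
    if (is.null(age)) stop_mse("`age` required for MAR-on-age", "mse_bad_argument")
    z <- as.numeric(scale(age))
    a <- stats::uniroot(function(a) mean(stats::plogis(a + m$age_slope * z)) -
                          m$overall_rate, c(-30, 30))$root
    stats::plogis(a + m$age_slope * z)
  }
  with_seed(substream_seed(seed, "missingness"), {
    mask <- matrix(stats::runif(n * J) < prob, n, J)  # prob recycles by row
    for (j in seq_len(J)) tab[mask[, j], j] <- NA
  })
  tab
}

#' Connectome generator specification
#'
#' @param n_rois Number of ROIs (>= 4).
#' @param effect_edges data.frame with columns `i`, `j`, `slope`: edges whose
#'   Fisher-z value depends linearly on the exposure score. i != j, no
#'   duplicates.
#' @param noise_sd Edge noise SD (> 0; may be 0 for degenerate limits).
#' @param covariate_edges Optional data.frame `i`, `j`, `covariate`, `slope`
#'   for edges depending on a covariate (confound fixtures).
#' @return Object of class `connectome_spec`.
#' @export
connectome_spec <- function(n_rois, effect_edges = NULL, noise_sd = 1,
                            covariate_edges = NULL) {
  check_number(n_rois, "n_rois", lower = 4, integer = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(effect_edges)) {
    if (any(effect_edges$i == effect_edges$j))
      stop_mse("effect edges must have i != j", "mse_bad_argument")
    key <- paste(pmin(effect_edges$i, effect_edges$j),
                 pmax(effect_edges$i, effect_edges$j))
    if (anyDuplicated(key))
      stop_mse("duplicate effect edge", "mse_duplicate_edge")
    if (any(c(effect_edges$i, effect_edges$j) > n_rois))
      stop_mse("edge index out of range", "mse_bad_argument")
  }
  structure(list(n_rois = n_rois, effect_edges = effect_edges,
                 noise_sd = noise_sd, covariate_edges = covariate_edges),
            class = "connectome_spec")
}

#' Generate synthetic Fisher-z connectomes
#'
#' Every edge is symmetric zero-diagonal noise N(0, noise_sd); each effect
#' edge additionally receives `slope * exposure` (and covariate contributions
#' if specified), so effect edges have the stated population slope and
#' off-effect edges are pure noise.
#'
#' @param spec A [connectome_spec()].
#' @param exposure Per-subject exposome scores.
#' @param covariates Optional data.frame (columns referenced by
#'   `covariate_edges`); also attached to the returned set.
#' @param seed Integer seed.
#' @return A [connectome_set()].
#' @export
generate_connectomes <- function(spec, exposure, covariates = NULL, seed = 1) {
  stopifnot(inherits(spec, "connectome_spec"))
  n <- length(exposure)
  if (!is.null(covariates) && nrow(covariates) != n)
    stop_mse("covariates must have one row per subject", "mse_bad_argument")
  p <- spec$n_rois
  mats <- with_seed(substream_seed(seed, "connectomes"), {
    lapply(seq_len(n), function(s) {
      m <- matrix(0, p, p)
      m[upper.tri(m)] <- stats::rnorm(p * (p - 1) / 2, 0, spec$noise_sd)
      if (!is.null(spec$effect_edges)) {
        for (r in seq_len(nrow(spec$effect_edges))) {
          e <- spec$effect_edges[r, ]
          i <- min(e$i, e$j); j <- max(e$i, e$j)
          m[i, j] <- m[i, j] + e$slope * exposure[s]
        }
      }
      if (!is.null(spec$covariate_edges)) {
        for (r in seq_len(nrow(spec$covariate_edges))) {
          e <- spec$covariate_edges[r, ]
          i <- min(e$i, e$j); j <- max(e$i, e$j)
          m[i, j] <- m[i, j] + e$slope * covariates[[e$covariate]][s]
        }
      }
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
  })
  connectome_set(mats, covariates = covariates)
}

#' Generate a framewise-displacement motion trace
#'
#' Baseline FD values are drawn uniformly in [0.4, 1.6] x `baseline` mm
#' (safely below a 0.2 mm threshold for the default baseline of 0.05 mm);
#' spike frames are set exactly to `spike_amplitude`, so FD exceeds 0.2 mm at
#' precisely the spike frames whenever the amplitude is above threshold.
#'
#' @param n_frames Number of frames (>= 20).
#' @param spike_frames Integer indices of spiked frames (within range).
#' @param spike_amplitude FD value at spike frames, in mm.
#' @param baseline Baseline mean FD in mm (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `motion_trace` with elements `fd`, `spike_frames`.
#' @export
generate_motion_trace <- function(n_frames, spike_frames = integer(0),
                                  spike_amplitude = 0.5, baseline = 0.05,
                                  seed = 1) {
  check_number(n_frames, "n_frames", lower = 20, integer = TRUE)
  if (length(spike_frames) &&
      (min(spike_frames) < 1 || max(spike_frames) > n_frames))
    stop_mse("spike index out of range", "mse_bad_argument")
  fd <- with_seed(substream_seed(seed, "motion"),
                  stats::runif(n_frames, 0.4 * baseline, 1.6 * baseline))
  fd[spike_frames] <- spike_amplitude
  structure(list(fd = fd, spike_frames = sort(unique(as.integer(spike_frames)))),
            class = "motion_trace")
}

#' Simulate standardized indicator/outcome data from the one-factor model
#'
#' Direct draw from the population model the engine estimates: indicators
#' x_j = lambda_j eta + e_j and outcomes y_k = beta_k eta + zeta_k with unit
#' total variances, eta ~ N(0, 1). Used for parameter-recovery and oracle
#' tests where the questionnaire machinery would only add noise.
#'
#' @param n Sample size.
#' @param loadings Named standardized loadings, |lambda| <= 1.
#' @param paths Named standardized paths, |beta| < 1.
#' @param seed Integer seed.
#' @return data.frame with one column per indicator and outcome, plus
#'   attribute `latent` (the true factor values).
#' @export
simulate_indicator_data <- function(n, loadings = default_loadings(),
                                    paths = c(cognition = 0.261,
                                              functional_ability = 0.079,
                                              neuropsychiatric = 0.105),
                                    seed = 1) {
  if (any(abs(loadings) > 1) || any(abs(paths) >= 1))
    stop_mse("standardized coefficients out of range", "mse_bad_argument")
  with_seed(substream_seed(seed, "indicator-data"), {
    eta <- stats::rnorm(n)
    out <- lapply(loadings, function(l)
      l * eta + stats::rnorm(n, 0, sqrt(1 - l^2)))
    names(out) <- names(loadings)
    for (k in names(paths))
      out[[k]] <- paths[k] * eta + stats::rnorm(n, 0, sqrt(1 - paths[k]^2))
    df <- as.data.frame(out)
    attr(df, "latent") <- eta
    df
  })
}
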
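# ROI-to-ROI connectivity association with the exposome score, per-ROI FDR,
# binarized degree centrality, and fMRI quality-control computations.

#' Fisher z-transform of correlation coefficients
#'
#' @param r Correlations, |r| < 1.
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop_mse("|r| must be < 1 for the Fisher z-transform", "mse_bad_argument")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z values.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Bundle subject-level connectomes with covariates
#'
#' @param matrices List of symmetric ROI x ROI matrices (zero diagonal) of
#'   Fisher-z connectivity, one per subject.
#' @param covariates Optional data.frame of per-subject covariates
#'   (e.g. age, sex, scanner dummies).
#' @param roi_labels Optional ROI labels; defaults to `roi_1..roi_p`.
#' @param subject_id Optional subject identifiers.
#' @param tol Symmetry tolerance.
#' @return Object of class `connectome_set`.
#' @export
connectome_set <- function(matrices, covariates = NULL, roi_labels = NULL,
                           subject_id = NULL, tol = 1e-12) {
  p <- unique(vapply(matrices, nrow, 1L))
  if (length(p) != 1L)
    stop_mse("all connectomes must share one ROI count", "mse_bad_argument")
  for (m in matrices) {
    if (max(abs(m - t(m))) > tol)
      stop_mse("connectome matrices must be symmetric", "mse_asymmetric")
    if (max(abs(diag(m))) > tol)
      stop_mse("connectome diagonals must be zero", "mse_bad_argument")
  }
  roi_labels <- roi_labels %||% paste0("roi_", seq_len(p))
  subject_id <- subject_id %||% paste0("s", seq_along(matrices))
  if (!is.null(covariates) && nrow(covariates) != length(matrices))
    stop_mse("covariates must have one row per subject", "mse_bad_argument")
  structure(list(matrices = matrices, covariates = covariates,
                 roi_labels = roi_labels, subject_id = subject_id,
                 n_rois = p),
            class = "connectome_set")
}

#' @export
print.connectome_set <- function(x, ...) {
  cat(sprintf("<connectome_set> %d subjects, %d x %d ROIs\n",
              length(x$matrices), x$n_rois, x$n_rois))
  invisible(x)
}

#' Edge-wise association between connectivity and a predictor
#'
#' Per-edge ordinary least squares of the Fisher-z edge value on the exposome
#' score plus covariates of no interest; reports the two-sided t statistic and
#' p-value of the predictor coefficient for every upper-triangle edge,
#' vectorized across edges through one shared design decomposition.
#'
#' @param cset A [connectome_set()].
#' @param predictor Numeric per-subject exposome scores.
#' @param covariates Design data.frame of covariates of no interest; defaults
#'   to `cset$covariates`. Pass `NULL` explicitly for an unadjusted model.
#' @return Object of class `edge_stats`: symmetric matrices `t` and `p`
#'   (diagonal NA), plus `df` and the edge index.
#' @export
edge_association <- function(cset, predictor, covariates) {
  n <- length(cset$matrices)
  if (length(predictor) != n)
    stop_mse("predictor length must equal the number of subjects", "mse_bad_argument")
  if (missing(covariates)) covariates <- cset$covariates
  X <- cbind(intercept = 1, predictor = predictor)
  if (!is.null(covariates))
    X <- cbind(X, as.matrix(stats::model.matrix(~ . - 1, data = covariates)))
  k <- ncol(X)
  if (n <= k)
    stop_mse("need more subjects than design columns", "mse_bad_argument")
  if (qr(X)$rank < k)
    stop_mse("rank-deficient design", "mse_rank_deficient")
  p <- cset$n_rois
  ut <- which(upper.tri(matrix(0, p, p)))
  Y <- vapply(cset$matrices, function(m) m[ut], numeric(length(ut)))
  Y <- t(Y)                                  # n x n_edges
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)            # k x n_edges
  R <- Y - X %*% B
  df <- n - k
  sigma2 <- colSums(R^2) / df
  pi <- which(colnames(X) == "predictor")
  se <- sqrt(sigma2 * XtXinv[pi, pi])
  tval <- B[pi, ] / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tm <- matrix(NA_real_, p, p, dimnames = list(cset$roi_labels, cset$roi_labels))
  pm <- tm
  tm[ut] <- tval; pm[ut] <- pval
  tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
  pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  structure(list(t = tm, p = pm, df = df, n = n), class = "edge_stats")
}

bh_reject <- function(p, q) {
  # Benjamini-Hochberg step-up on a vector of p-values; returns logical mask.
  m <- length(p)
  o <- order(p)
  thr <- q * seq_len(m) / m
  k <- which(p[o] <= thr)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

#' Per-ROI FDR mask of significant edges
#'
#' Benjamini-Hochberg step-up applied separately within each ROI's row of
#' n_rois - 1 p-values (connection-level correction for the size of each ROI's
#' row of the matrix), then symmetrized by the union of the two row decisions.
#' A global-BH alternative over all upper-triangle edges is available via
#' `method = "global"`.
#'
#' @param stats An `edge_stats` object.
#' @param q FDR level (default 0.05).
#' @param method `"row"` (default, per-ROI) or `"global"`.
#' @param symmetrize Union-symmetrize the per-row decisions (default TRUE).
#'   `FALSE` returns the raw row-family decisions (`mask[i, j]` = edge j
#'   rejected within ROI i's family), the quantity whose false discovery rate
#'   the step-up procedure controls per row.
#' @return Logical matrix (diagonal FALSE); symmetric unless
#'   `symmetrize = FALSE`.
#' @export
row_fdr_mask <- function(stats, q = 0.05, method = c("row", "global"),
                         symmetrize = TRUE) {
  method <- match.arg(method)
  P <- stats$p
  p <- nrow(P)
  mask <- matrix(FALSE, p, p, dimnames = dimnames(P))
  if (method == "global") {
    ut <- which(upper.tri(P))
    mask[ut] <- bh_reject(P[ut], q)
    mask[lower.tri(mask)] <- t(mask)[lower.tri(mask)]
    return(mask)
  }
  for (i in seq_len(p)) {
    idx <- setdiff(seq_len(p), i)
    mask[i, idx] <- mask[i, idx] | bh_reject(P[i, idx], q)
  }
  if (symmetrize) mask | t(mask) else mask
}

#' Binarized degree centrality from a significance mask
#'
#' Each significant edge (positively or negatively weighted) contributes a
#' count of one to both endpoint ROIs.
#'
#' @param mask Symmetric logical matrix of significant edges.
#' @param t_matrix Optional t matrix; when given, counts are split by sign.
#' @return data.frame with `roi`, `degree` and, if `t_matrix` is supplied,
#'   `degree_pos` / `degree_neg`.
#' @export
degree_centrality <- function(mask, t_matrix = NULL) {
  mask <- as.matrix(mask)
  if (any(mask != t(mask)))
    stop_mse("mask must be symmetric", "mse_asymmetric")
  diag(mask) <- FALSE
  roi <- rownames(mask) %||% paste0("roi_", seq_len(nrow(mask)))
  out <- data.frame(roi = roi, degree = as.integer(rowSums(mask)),
                    stringsAsFactors = FALSE)
  if (!is.null(t_matrix)) {
    out$degree_pos <- as.integer(rowSums(mask & t_matrix > 0))
    out$degree_neg <- as.integer(rowSums(mask & t_matrix < 0))
  }
  out
}

#' Motion scrubbing and subject-level quality control
#'
#' Flags frames whose framewise displacement exceeds `fd_threshold` (default
#' 0.2 mm, stricter than conventional scrubbing) or whose global-signal
#' z-score exceeds `gs_z_threshold`; computes the artifact-free proportion and
#' marks the subject for exclusion when it falls strictly below `min_keep`
#' (exactly 70% artifact-free frames is retained).
#'
#' @param trace A `motion_trace` (see [generate_motion_trace()]) or numeric
#'   vector of framewise displacement in mm.
#' @param global_signal Optional per-frame global-signal values; z-scored
#'   internally.
#' @param fd_threshold FD threshold in mm.
#' @param gs_z_threshold Global-signal |z| threshold.
#' @param min_keep Minimum retained artifact-free proportion.
#' @return List of class `qc_report`: `fd`, `flagged`, `kept_mask`,
#'   `artifact_free_proportion`, `excluded`.
#' @export
scrub_and_qc <- function(trace, global_signal = NULL, fd_threshold = 0.2,
                         gs_z_threshold = 5, min_keep = 0.70) {
  fd <- if (inherits(trace, "motion_trace")) trace$fd else as.numeric(trace)
  if (length(fd) < 20L)
    stop_mse("need at least 20 frames", "mse_bad_argument")
  flagged <- fd > fd_threshold
  if (!is.null(global_signal)) {
    z <- as.numeric(scale(global_signal))
    flagged <- flagged | (abs(z) > gs_z_threshold)
  }
  prop <- mean(!flagged)
  structure(list(fd = fd, flagged = flagged, kept_mask = !flagged,
                 artifact_free_proportion = prop,
                 excluded = prop < min_keep),
            class = "qc_report")
}

#' Spatial SNR and segmented temporal SNR
#'
#' Spatial SNR is mean(signal)/sd(signal) over the supplied values. Temporal
#' SNR is computed per non-overlapping segment of `segment_len` frames
#' (default 20 repetition times) as segment mean over segment standard
#' deviation; zero-variance segments are returned as NA with a flag.
#'
#' @param series Numeric vector (time series or voxel intensities).
#' @param segment_len Segment length in frames (>= 2).
#' @return List with `snr`, `tsnr` (one value per complete segment),
#'   `undefined_segments` (logical).
#' @export
signal_quality <- function(series, segment_len = 20) {
  check_number(segment_len, "segment_len", lower = 2, integer = TRUE)
  series <- as.numeric(series)
  if (length(series) < segment_len)
    stop_mse("series shorter than one segment", "mse_bad_argument")
  sds <- stats::sd(series)
  snr <- if (sds == 0) NA_real_ else mean(series) / sds
  nseg <- length(series) %/% segment_len
  tsnr <- undef <- rep(NA, nseg)
  for (s in seq_len(nseg)) {
    seg <- series[((s - 1) * segment_len + 1):(s * segment_len)]
    sdg <- stats::sd(seg)
    undef[s] <- sdg == 0
    tsnr[s] <- if (sdg == 0) NA_real_ else mean(seg) / sdg
  }
  list(snr = snr, tsnr = tsnr, undefined_segments = as.logical(undef))
}
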
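# Questionnaire-to-composite scoring: min-max scaling with polarity handling,
# dimension averaging, outcome inversion, and the per-group feature rescale
# used as a scanner-harmonization sensitivity step.
#
# Direction convention: after scaling, HIGHER values indicate LOWER social
# adversity (canonical here; the opposite coding is available through the
# `higher_is_less_adverse` flag). Items whose raw value increases with
# adversity carry polarity "adversity_high" and are flipped during scaling.

#' Min-max scale an item to [0, 1] with polarity handling
#'
#' Maps the observed minimum to 0 and maximum to 1, then flips
#' `adversity_high` items so that the output convention is higher = less
#' adversity. Invariant to affine transforms of the native scale. Missing
#' values are passed through.
#'
#' @param values Numeric vector on the item's native scale.
#' @param polarity `"adversity_low"` (raw value increases with well-being) or
#'   `"adversity_high"` (raw value increases with adversity; flipped).
#' @return Numeric vector in [0, 1].
#' @export
min_max_scale <- function(values, polarity = c("adversity_low", "adversity_high")) {
  polarity <- match.arg(polarity)
  obs <- values[!is.na(values)]
  if (!length(obs))
    stop_mse("no observed values to scale", "mse_degenerate_item")
  rng <- range(obs)
  if (rng[1] == rng[2])
    stop_mse("constant item: max equals min", "mse_degenerate_item")
  out <- (values - rng[1]) / (rng[2] - rng[1])
  if (polarity == "adversity_high") out <- 1 - out
  out
}

#' Item metadata table constructor
#'
#' @param item_id Item identifiers (unique, matching item-table columns).
#' @param dimension One of [mse_dimensions()] per item.
#' @param polarity `"adversity_low"` or `"adversity_high"` per item.
#' @param excluded Logical; items flagged as dementia-confounded (e.g.
#'   technology access, employment, current salary) and dropped from scoring.
#' @return data.frame of class `item_meta`.
#' @export
item_meta <- function(item_id, dimension, polarity = "adversity_low",
                      excluded = FALSE) {
  if (anyDuplicated(item_id))
    stop_mse("item ids must be unique", "mse_bad_argument")
  bad <- setdiff(unique(dimension), mse_dimensions())
  if (length(bad))
    stop_mse(sprintf("unknown dimension(s): %s", paste(bad, collapse = ", ")),
             "mse_bad_argument")
  structure(data.frame(item_id = as.character(item_id),
                       dimension = as.character(dimension),
                       polarity = rep_len(polarity, length(item_id)),
                       excluded = rep_len(excluded, length(item_id)),
                       stringsAsFactors = FALSE),
            class = c("item_meta", "data.frame"))
}

#' Scale all items and average them into the ten dimension composites
#'
#' Applies [min_max_scale()] per item (constant items are dropped with a
#' warning, excluded items skipped) and averages scaled items within each
#' dimension, optionally with nonnegative per-item weights normalized within
#' dimension. Requires complete data: impute first (see
#' [impute_chained_pmm()]).
#'
#' @param items data.frame/matrix of raw item responses (subjects x items).
#' @param meta An [item_meta()] table covering every scored column.
#' @param weights Optional named nonnegative per-item weights.
#' @param subject_id Optional subject identifiers.
#' @return data.frame of class `dimension_scores`: `subject_id` plus one
#'   column in [0, 1] per dimension present; attribute
#'   `higher_is_less_adverse = TRUE`.
#' @export
compute_dimension_scores <- function(items, meta, weights = NULL,
                                     subject_id = NULL) {
  items <- as.data.frame(items)
  use <- meta[!meta$excluded & meta$item_id %in% names(items), , drop = FALSE]
  if (!nrow(use))
    stop_mse("no scoreable items", "mse_bad_argument")
  if (anyNA(items[, use$item_id]))
    stop_mse("missing values present; impute before scoring", "mse_missing_values")
  scaled <- list()
  for (i in seq_len(nrow(use))) {
    id <- use$item_id[i]
    s <- tryCatch(min_max_scale(items[[id]], use$polarity[i]),
                  mse_degenerate_item = function(e) {
                    warning(sprintf("dropping constant item '%s'", id),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(s)) scaled[[id]] <- s
  }
  use <- use[use$item_id %in% names(scaled), , drop = FALSE]
  dims <- intersect(mse_dimensions(), unique(use$dimension))
  out <- data.frame(subject_id = subject_id %||% paste0("s", seq_len(nrow(items))),
                    stringsAsFactors = FALSE)
  for (d in dims) {
    ids <- use$item_id[use$dimension == d]
    w <- if (is.null(weights)) rep(1, length(ids)) else {
      wv <- weights[ids]
      if (anyNA(wv) || any(wv < 0))
        stop_mse("weights must be nonnegative and cover all items",
                 "mse_bad_argument")
      as.numeric(wv)
    }
    if (sum(w) == 0)
      stop_mse(sprintf("dimension '%s' has zero total weight", d),
               "mse_bad_argument")
    w <- w / sum(w)
    m <- as.matrix(items[, ids, drop = FALSE])
    for (j in seq_along(ids)) m[, j] <- scaled[[ids[j]]]
    out[[d]] <- as.numeric(m %*% w)
  }
  attr(out, "higher_is_less_adverse") <- TRUE
  class(out) <- c("dimension_scores", "data.frame")
  out
}

#' Invert a bounded clinical instrument score
#'
#' Returns `instrument_max - value`, so that higher always means better
#' function / fewer symptoms, aligning functional-ability and neuropsychiatric
#' scores with cognition. Applying it twice restores the input.
#'
#' @param values Values in [0, instrument_max].
#' @param instrument_max Upper bound of the instrument (PFAQ 30, NPI-Q 36).
#' @return Inverted values.
#' @export
invert_outcome <- function(values, instrument_max) {
  check_number(instrument_max, "instrument_max", lower = 0, strict_lower = TRUE)
  if (any(values < 0 | values > instrument_max, na.rm = TRUE))
    stop_mse("values outside [0, instrument_max]", "mse_bad_argument")
  instrument_max - values
}

#' Rescale each feature to [0, 1] within each group
#'
#' Harmonization sensitivity step: features are min-max scaled between the
#' minimum and maximum specific to each group (e.g. scanner type), removing
#' between-group location and scale differences. Features constant within a
#' group are left unscaled there, with a warning.
#'
#' @param x Numeric matrix or data.frame, subjects x features.
#' @param group_labels Grouping vector of length nrow(x) (>= 2 subjects per
#'   group).
#' @return Matrix of the same shape.
#' @export
per_group_feature_rescale <- function(x, group_labels) {
  x <- as.matrix(x)
  group_labels <- as.character(group_labels)
  if (length(group_labels) != nrow(x))
    stop_mse("one group label per row required", "mse_bad_argument")
  if (any(table(group_labels) < 2))
    stop_mse("each group needs at least 2 subjects", "mse_bad_argument")
  out <- x
  for (g in unique(group_labels)) {
    rows <- group_labels == g
    for (j in seq_len(ncol(x))) {
      rng <- range(x[rows, j])
      if (rng[1] == rng[2]) {
        warning(sprintf("feature %d constant within group '%s'; left unscaled",
                        j, g), call. = FALSE)
      } else {
        out[rows, j] <- (x[rows, j] - rng[1]) / (rng[2] - rng[1])
      }
    }
  }
  out
}
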
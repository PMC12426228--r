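#' @keywords internal
"_PACKAGE"

# Internal input-checking helpers. All user-facing errors are signalled with
# a condition class so callers/tests can discriminate failure modes.

stop_mse <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "msexposome_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mse(sprintf("`%s` must be a single finite number", name), "mse_bad_argument")
  if (integer && x != round(x))
    stop_mse(sprintf("`%s` must be an integer", name), "mse_bad_argument")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_mse(sprintf("`%s` = %g is out of range [%g, %g]", name, x, lower, upper),
             "mse_bad_argument")
  invisible(x)
}

# Fan one user-visible seed out into independent per-stage substreams, so that
# e.g. item noise and missingness masks are reproducible stage by stage.
# Substream seeds are kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 2654435.0) %% 1000003
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical names of the ten social exposome dimensions
#'
#' The composite dimensions of the multidimensional social exposome (MSE):
#' education, food insecurity, financial status, assets, access to healthcare,
#' childhood labor, subjective socioeconomic status, childhood experiences,
#' traumatic events, and relationships.
#'
#' @return Character vector of length 10.
#' @export
mse_dimensions <- function() {
  c("education", "food_insecurity", "financial_status", "assets",
    "access_healthcare", "childhood_labor", "subjective_ses",
    "childhood_experiences", "traumatic_events", "relations")
}

#' Canonical names of the three clinical outcomes
#'
#' @return Character vector: cognition (MMSE-like, 0-30), functional ability
#'   (PFAQ-like, 0-30, inverted upstream), neuropsychiatric symptoms
#'   (NPI-Q-like, 0-36, inverted upstream).
#' @export
mse_outcomes <- function() {
  c("cognition", "functional_ability", "neuropsychiatric")
}
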
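# Internal helpers shared across modules.

# Round half away from zero (round(2.5) in R rounds to even; budgets and
# class quotas need the away-from-zero rule so counts are exactly testable).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from a single master seed through this
#' counter scheme: every stage (prevalence sampling, cohort rejection
#' sampling, fold assignment, each noise-injection cell) gets its own derived
#' seed, so any stage can be reproduced in isolation from the manifest.
#'
#' @param master integer master seed.
#' @param ... integer stream indices (stage code, mechanism index, proportion
#'   index, replicate index, ...).
#' @return a positive integer seed below 2^31.
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 3, 2, 1)
#' @export
derive_seed <- function(master, ...) {
  idx <- as.double(c(...))
  s <- as.double(master) %% 2147483629
  for (k in seq_along(idx)) {
    s <- (s * 69069 + idx[k] * 7907 + k * 104729) %% 2147483629
  }
  as.integer(s) + 1L
}

# Validate a {0,1} feature matrix with unique column labels.
assert_binary_matrix <- function(x, what = "feature matrix") {
  if (!is.matrix(x)) {
    stop(what, " must be a matrix", call. = FALSE)
  }
  if (anyNA(x)) {
    stop(what, " contains missing values", call. = FALSE)
  }
  if (!all(x == 0L | x == 1L)) {
    bad <- which(!(x == 0L | x == 1L), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s has a non-binary cell at row %d, column %d",
                 what, bad[[1L]], bad[[2L]]), call. = FALSE)
  }
  invisible(x)
}

# Scalar checks used by the config constructors.
is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_proportion <- function(x, open_low = FALSE, open_high = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x)
  if (!ok) return(FALSE)
  lo <- if (open_low) x > 0 else x >= 0
  hi <- if (open_high) x < 1 else x <= 1
  lo && hi
}
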
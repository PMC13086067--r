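# Attribute-noise injection.
#
# Three mechanisms, modelled on Rubin's missing-data taxonomy, perturb the
# binary feature matrix only (the outcome is never touched):
#
#   NCAR  noise completely at random: uniformly chosen cells are toggled;
#   NAR   noise at random: features are split into "changeable" and
#         "unchangeable" sets and the changeable cells of the instances with
#         the highest unchangeable sums are flipped;
#   NNAR  noise not at random: randomly chosen zero cells are set to one
#         (the flip depends on the hidden original value).
#
# Every mechanism spends an exact cell budget B = round(p * n * m), halves
# rounded away from zero, and returns the boolean mask of altered cells.

#' Specification of one noise-injection cell
#'
#' @param mechanism one of `"NCAR"`, `"NAR"`, `"NNAR"`.
#' @param proportion nominal noise proportion `p` in `[0, 1)`, interpreted as
#'   a fraction of all feature-matrix cells and enforced as the exact budget
#'   `B = round(p * n * m)`.
#' @param seed integer seed for the injection's own random stream.
#' @param changeable_fraction NAR only: fraction `c` of features assigned to
#'   the changeable set (default 0.5). The budget is infeasible when
#'   `p > c` (up to rounding).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(mechanism = c("NCAR", "NAR", "NNAR"),
                       proportion = 0,
                       seed = 1L,
                       changeable_fraction = 0.5) {
  mechanism <- match.arg(mechanism)
  if (!is_proportion(proportion)) {
    stop("proportion must lie in [0, 1)", call. = FALSE)
  }
  if (!is_proportion(changeable_fraction, open_low = TRUE)) {
    stop("changeable_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (mechanism == "NAR" && proportion > changeable_fraction) {
    stop(sprintf(
      "NAR budget infeasible: proportion (%.3f) exceeds changeable_fraction (%.3f)",
      proportion, changeable_fraction), call. = FALSE)
  }
  structure(
    list(mechanism = mechanism, proportion = proportion,
         seed = as.integer(seed), changeable_fraction = changeable_fraction),
    class = "noise_spec"
  )
}

flip_budget <- function(p, n, m) {
  as.integer(round_half_away(p * n * m))
}

empty_injection <- function(matrix) {
  mask <- matrix(FALSE, nrow(matrix), ncol(matrix),
                 dimnames = dimnames(matrix))
  list(noisy = matrix, mask = mask)
}

#' Inject attribute noise into a binary feature matrix
#'
#' `inject_noise()` dispatches on `spec$mechanism`; the three mechanism
#' functions can also be called directly. All of them toggle exactly
#' `round(p * n * m)` cells and return both the noisy matrix and the flip
#' mask. The outcome vector is never part of the interface.
#'
#' @param matrix integer 0/1 matrix (instances x features).
#' @param spec a [noise_spec()].
#' @return a list with elements `noisy` (same shape, 0/1) and `mask`
#'   (logical, `TRUE` where a cell was altered).
#' @examples
#' X <- matrix(0L, 10, 10)
#' out <- inject_noise(X, noise_spec("NCAR", 0.05, seed = 1))
#' sum(out$mask)  # exactly 5 cells
#' @export
inject_noise <- function(matrix, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  switch(spec$mechanism,
         NCAR = inject_ncar(matrix, spec),
         NAR = inject_nar(matrix, spec),
         NNAR = inject_nnar(matrix, spec))
}

#' @rdname inject_noise
#' @export
inject_ncar <- function(matrix, spec) {
  assert_binary_matrix(matrix)
  stopifnot(spec$mechanism == "NCAR")
  n <- nrow(matrix); m <- ncol(matrix)
  B <- flip_budget(spec$proportion, n, m)
  if (B == 0L) return(empty_injection(matrix))
  cells <- withr::with_seed(spec$seed, sample.int(n * m, B))
  noisy <- matrix
  noisy[cells] <- 1L - noisy[cells]
  mask <- matrix(FALSE, n, m, dimnames = dimnames(matrix))
  mask[cells] <- TRUE
  list(noisy = noisy, mask = mask)
}

#' @rdname inject_noise
#' @export
inject_nar <- function(matrix, spec) {
  assert_binary_matrix(matrix)
  stopifnot(spec$mechanism == "NAR")
  n <- nrow(matrix); m <- ncol(matrix)
  size_c <- as.integer(round_half_away(spec$changeable_fraction * m))
  if (size_c < 1L || m - size_c < 1L) {
    stop("NAR requires at least one changeable and one unchangeable feature",
         call. = FALSE)
  }
  B <- flip_budget(spec$proportion, n, m)
  if (B > n * size_c) {
    stop(sprintf(
      "NAR budget infeasible: %d flips requested but only %d changeable cells",
      B, n * size_c), call. = FALSE)
  }
  if (B == 0L) return(empty_injection(matrix))

  res <- withr::with_seed(spec$seed, {
    changeable <- sort(sample.int(m, size_c))
    unchangeable <- setdiff(seq_len(m), changeable)
    usum <- rowSums(matrix[, unchangeable, drop = FALSE])
    ranking <- order(-usum, seq_len(n))
    full <- B %/% size_c
    rem <- B %% size_c
    rows <- rep(ranking[seq_len(full)], each = size_c)
    cols <- rep(changeable, times = full)
    if (rem > 0L) {
      partial <- ranking[full + 1L]
      pick <- changeable[sample.int(size_c, rem)]
      rows <- c(rows, rep(partial, rem))
      cols <- c(cols, pick)
    }
    list(rows = rows, cols = cols)
  })
  idx <- cbind(res$rows, res$cols)
  noisy <- matrix
  noisy[idx] <- 1L - noisy[idx]
  mask <- matrix(FALSE, n, m, dimnames = dimnames(matrix))
  mask[idx] <- TRUE
  list(noisy = noisy, mask = mask)
}

#' @rdname inject_noise
#' @export
inject_nnar <- function(matrix, spec) {
  assert_binary_matrix(matrix)
  stopifnot(spec$mechanism == "NNAR")
  n <- nrow(matrix); m <- ncol(matrix)
  B <- flip_budget(spec$proportion, n, m)
  if (B == 0L) return(empty_injection(matrix))
  zeros <- which(matrix == 0L)
  if (length(zeros) < B) {
    stop(sprintf(
      "NNAR budget infeasible: %d zero cells available but %d flips requested",
      length(zeros), B), call. = FALSE)
  }
  sel <- withr::with_seed(spec$seed,
                          zeros[sample.int(length(zeros), B)])
  noisy <- matrix
  noisy[sel] <- 1L
  mask <- matrix(FALSE, n, m, dimnames = dimnames(matrix))
  mask[sel] <- TRUE
  list(noisy = noisy, mask = mask)
}

#' Realized noise proportion between two matrices
#'
#' Hamming distance divided by the cell count; a validation utility for
#' checking that an injection spent exactly its budget.
#'
#' @param matrix,noisy same-shape binary matrices.
#' @return a proportion in `[0, 1]`.
#' @export
realized_noise <- function(matrix, noisy) {
  assert_binary_matrix(matrix)
  assert_binary_matrix(noisy, "noisy matrix")
  if (!identical(dim(matrix), dim(noisy))) {
    stop("matrices have different shapes", call. = FALSE)
  }
  mean(matrix != noisy)
}

#' Inject noise into a cohort's features
#'
#' Convenience wrapper: applies [inject_noise()] to `cohort$features` and
#' returns a new cohort with the identical (never perturbed) outcome.
#'
#' @param cohort a `cohort`.
#' @param spec a [noise_spec()].
#' @return list with elements `cohort` (noisy) and `mask`.
#' @export
inject_cohort <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort"))
  out <- inject_noise(cohort$features, spec)
  noisy <- cohort
  noisy$features <- out$noisy
  list(cohort = noisy, mask = out$mask)
}
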
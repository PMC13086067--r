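# Synthetic case-control cohort generator.
#
# Emulates an EHR-style case-control extract: ~180 binary comorbidity
# "code block" indicators with heterogeneous prevalences, a balanced binary
# outcome, and a sparse set of planted log-odds effects that serve as the
# ground truth for every downstream stability analysis.

# Default planted effects: the ten strongest code blocks of the reference
# noise-free logistic fit, keyed by block label.
default_planted_effects <- function() {
  c("117" = 0.98, "63" = 0.876, "34" = 0.856, "2" = 0.826, "106" = 0.745,
    "175" = 0.728, "9" = 0.691, "71" = 0.608, "67" = 0.599, "171" = 0.579)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_instances total number of instances (cases + controls).
#' @param n_features number of binary features; labels are `"1"` ...
#'   `as.character(n_features)`, mimicking ICD code-block identifiers.
#' @param planted_effects named numeric vector of true log-odds effects,
#'   keyed by feature label; unnamed features have effect 0. The default
#'   plants the ten reference block effects (0.98 down to 0.579) on blocks
#'   117, 63, 34, 2, 106, 175, 9, 71, 67 and 171.
#' @param prevalence_shape length-2 positive vector `(a, b)`: feature
#'   prevalences are drawn from `Beta(a, b)`. The default `(1, 9)` gives a
#'   mean prevalence of 0.1, typical for comorbidity indicators.
#' @param case_fraction fraction of instances that are cases, in (0, 1).
#'   The case quota is `round(case_fraction * n_instances)` with halves
#'   rounded away from zero.
#' @param min_prevalence lower truncation of the prevalence prior (default
#'   0.01, the conventional minimum-support filter for EHR code features).
#'   Draws below the floor are redrawn. Features rarer than this have too
#'   few positive cells for an unpenalized logistic fit to be identifiable,
#'   which would make coefficient-based impact scores meaningless; set to 0
#'   for the untruncated prior.
#' @param seed integer master seed for the generator.
#' @return an object of class `generator_config`.
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(n_instances = 6794L,
                             n_features = 180L,
                             planted_effects = default_planted_effects(),
                             prevalence_shape = c(1, 9),
                             case_fraction = 0.5,
                             min_prevalence = 0.01,
                             seed = 1L) {
  if (!is_count(n_instances, min = 2)) {
    stop("n_instances must be an integer >= 2", call. = FALSE)
  }
  if (!is_count(n_features, min = 2)) {
    stop("n_features must be an integer >= 2", call. = FALSE)
  }
  if (length(prevalence_shape) != 2L || !is.numeric(prevalence_shape) ||
      any(is.na(prevalence_shape)) || any(prevalence_shape <= 0)) {
    stop("prevalence_shape must be two positive reals (a, b)", call. = FALSE)
  }
  if (!is_proportion(case_fraction, open_low = TRUE, open_high = TRUE)) {
    stop("case_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(min_prevalence) || length(min_prevalence) != 1L ||
      is.na(min_prevalence) || min_prevalence < 0 || min_prevalence >= 0.5) {
    stop("min_prevalence must lie in [0, 0.5)", call. = FALSE)
  }
  if (!is_count(abs(seed), min = 0)) {
    stop("seed must be an integer", call. = FALSE)
  }
  labels <- as.character(seq_len(n_features))
  if (is.list(planted_effects)) {
    planted_effects <- unlist(planted_effects)
  }
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) || any(names(planted_effects) == "")) {
      stop("planted_effects must be a fully named vector", call. = FALSE)
    }
    missing <- setdiff(names(planted_effects), labels)
    if (length(missing)) {
      stop("planted_effects labels not among the feature labels: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_instances = as.integer(n_instances),
         n_features = as.integer(n_features),
         planted_effects = planted_effects,
         prevalence_shape = as.numeric(prevalence_shape),
         case_fraction = case_fraction,
         min_prevalence = min_prevalence,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Sample per-feature prevalences
#'
#' Draws one prevalence per feature from the configured Beta prior. Uses its
#' own derived sub-stream of the master seed, so the same config always
#' yields the same prevalences regardless of what else has been run.
#'
#' @param config a [generator_config()].
#' @return numeric vector of length `n_features`, named by feature label,
#'   each value in (0, 1).
#' @export
sample_prevalences <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  a <- config$prevalence_shape[1L]
  b <- config$prevalence_shape[2L]
  floor_p <- config$min_prevalence
  prev <- withr::with_seed(derive_seed(config$seed, 1L), {
    p <- rbeta(config$n_features, a, b)
    # truncated prior: redraw anything under the support floor
    for (i in 1:1000) {
      low <- which(p < floor_p)
      if (!length(low)) break
      p[low] <- rbeta(length(low), a, b)
    }
    if (any(p < floor_p)) {
      stop("prevalence prior puts almost no mass above min_prevalence",
           call. = FALSE)
    }
    p
  })
  # Guard against prevalences numerically equal to 0 or 1.
  prev <- pmin(pmax(prev, 1e-12), 1 - 1e-12)
  names(prev) <- as.character(seq_len(config$n_features))
  prev
}

# Population case probability for a given intercept: expectation of
# plogis(b0 + beta . x) over independent Bernoulli(prev) features. Exact by
# enumeration of the nonzero-effect combinations when few effects are
# planted; Monte Carlo otherwise.
population_case_rate <- function(b0, effects, prev, mc_draws = NULL) {
  nz <- which(effects != 0)
  if (!length(nz)) {
    return(plogis(b0))
  }
  if (is.null(mc_draws)) {
    k <- length(nz)
    combos <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
    lp <- drop(combos %*% effects[nz])
    logw <- drop(combos %*% log(prev[nz]) + (1 - combos) %*% log(1 - prev[nz]))
    sum(exp(logw) * plogis(b0 + lp))
  } else {
    mean(plogis(b0 + drop(mc_draws %*% effects[nz])))
  }
}

# Bisection for the intercept making the population case rate equal target.
calibrate_intercept <- function(effects, prev, target, seed) {
  nz <- which(effects != 0)
  mc_draws <- NULL
  if (length(nz) > 20L) {
    mc_draws <- withr::with_seed(
      seed,
      matrix(rbinom(200000L * length(nz), 1L, rep(prev[nz], each = 200000L)),
             nrow = 200000L)
    )
  }
  lo <- -40; hi <- 40
  f <- function(b0) population_case_rate(b0, effects, prev, mc_draws) - target
  if (f(lo) > 0 || f(hi) < 0) {
    stop("intercept calibration failed: target case rate unreachable",
         call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' Generate a balanced synthetic case-control cohort
#'
#' Features are drawn independently per instance as `Bernoulli(prevalence_j)`;
#' the outcome follows the logistic model `logit P(y = 1 | x) = b0 + sum_j
#' beta_j x_j` with the planted effects as `beta` and the intercept `b0`
#' calibrated by bisection so the population case probability equals
#' `case_fraction`. Instances are then rejection-sampled until the exact case
#' and control quotas are filled, and case and control rows are interleaved
#' in random order -- mirroring 1:1 case-control sampling. Because the
#' sampling is outcome-dependent only through the quotas, the logistic slopes
#' remain consistent and the planted effects are recoverable by an
#' unpenalized logistic fit.
#'
#' @param config a [generator_config()].
#' @return an object of class `cohort`: a list with elements `features`
#'   (integer 0/1 matrix, columns named by feature label), `outcome`
#'   (integer 0/1 vector, 1 = case) and `labels`. The sampled prevalences,
#'   calibrated intercept and config are attached as attributes.
#' @examples
#' cfg <- generator_config(n_instances = 200, n_features = 12,
#'                         planted_effects = c("3" = 1), seed = 7)
#' coh <- generate_cohort(cfg)
#' table(coh$outcome)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_instances
  m <- config$n_features
  labels <- as.character(seq_len(m))
  prev <- sample_prevalences(config)
  beta <- setNames(numeric(m), labels)
  beta[names(config$planted_effects)] <- config$planted_effects
  b0 <- calibrate_intercept(beta, prev, config$case_fraction,
                            seed = derive_seed(config$seed, 3L))

  n_case <- as.integer(round_half_away(config$case_fraction * n))
  n_ctrl <- n - n_case
  if (n_case < 1L || n_ctrl < 1L) {
    stop("case_fraction leaves one class empty at this n_instances",
         call. = FALSE)
  }

  res <- withr::with_seed(derive_seed(config$seed, 2L), {
    cases <- vector("list", 0L)
    ctrls <- vector("list", 0L)
    got_case <- 0L; got_ctrl <- 0L
    attempts <- 0L
    while ((got_case < n_case || got_ctrl < n_ctrl) && attempts < 200L) {
      attempts <- attempts + 1L
      b <- max(1000L, as.integer(ceiling(1.3 * (n_case - got_case + n_ctrl - got_ctrl))))
      X <- matrix(rbinom(b * m, 1L, rep(prev, each = b)), nrow = b, ncol = m)
      y <- rbinom(b, 1L, plogis(b0 + drop(X %*% beta)))
      if (got_case < n_case) {
        take <- which(y == 1L)
        take <- take[seq_len(min(length(take), n_case - got_case))]
        if (length(take)) {
          cases[[length(cases) + 1L]] <- X[take, , drop = FALSE]
          got_case <- got_case + length(take)
        }
      }
      if (got_ctrl < n_ctrl) {
        take <- which(y == 0L)
        take <- take[seq_len(min(length(take), n_ctrl - got_ctrl))]
        if (length(take)) {
          ctrls[[length(ctrls) + 1L]] <- X[take, , drop = FALSE]
          got_ctrl <- got_ctrl + length(take)
        }
      }
    }
    if (got_case < n_case || got_ctrl < n_ctrl) {
      stop(sprintf(
        "cohort generation failed after %d batches: have %d/%d cases, %d/%d controls",
        attempts, got_case, n_case, got_ctrl, n_ctrl), call. = FALSE)
    }
    X <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
    y <- c(rep(1L, n_case), rep(0L, n_ctrl))
    ord <- sample.int(n)
    list(X = X[ord, , drop = FALSE], y = y[ord])
  })

  features <- res$X
  storage.mode(features) <- "integer"
  colnames(features) <- labels
  structure(
    list(features = features, outcome = res$y, labels = labels),
    class = "cohort",
    prevalences = prev,
    intercept = b0,
    config = config
  )
}

# Construct/validate a cohort from raw components (used by the reader and
# by user-supplied data).
as_cohort <- function(features, outcome) {
  if (is.data.frame(features)) features <- as.matrix(features)
  assert_binary_matrix(features)
  if (is.null(colnames(features))) {
    stop("feature matrix must have column labels", call. = FALSE)
  }
  if (anyDuplicated(colnames(features))) {
    stop("duplicate feature labels: ",
         paste(unique(colnames(features)[duplicated(colnames(features))]),
               collapse = ", "), call. = FALSE)
  }
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(features)) {
    stop("outcome length does not match the number of instances", call. = FALSE)
  }
  if (anyNA(outcome) || !all(outcome %in% c(0L, 1L))) {
    bad <- which(is.na(outcome) | !(outcome %in% c(0L, 1L)))[1L]
    stop(sprintf("outcome has a non-binary value at row %d", bad),
         call. = FALSE)
  }
  storage.mode(features) <- "integer"
  structure(
    list(features = features, outcome = outcome,
         labels = colnames(features)),
    class = "cohort"
  )
}

# Row subset preserving class and labels (used by cross-validation).
subset_cohort <- function(cohort, idx) {
  structure(
    list(features = cohort$features[idx, , drop = FALSE],
         outcome = cohort$outcome[idx],
         labels = cohort$labels),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d instances x %d features; %d cases / %d controls\n",
              nrow(x$features), ncol(x$features),
              sum(x$outcome == 1L), sum(x$outcome == 0L)))
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' The on-disk format is a delimited table whose header row holds the feature
#' labels followed by a final column named `outcome`; all cells are strictly
#' 0/1. Comma is the default separator, tab is accepted on read, and a
#' `.gz` suffix triggers transparent compression.
#'
#' @param cohort a `cohort`.
#' @param path file path (`.csv`, `.tsv`, optionally `.gz`).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `cohort`. The round trip is an identity, cell for cell.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- data.table::as.data.table(cohort$features)
  df[["outcome"]] <- cohort$outcome
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("no such cohort file: ", path, call. = FALSE)
  }
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    data.table::fread(text = readLines(con), header = TRUE,
                      check.names = FALSE, colClasses = "numeric",
                      data.table = FALSE)
  } else {
    data.table::fread(path, header = TRUE, check.names = FALSE,
                      colClasses = "numeric", data.table = FALSE)
  }
  nm <- names(dt)
  if (!length(nm) || nm[length(nm)] != "outcome") {
    stop("cohort file must end with a column named 'outcome'", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate feature labels in header: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  feat <- as.matrix(dt[, -length(nm), drop = FALSE])
  if (anyNA(feat) || !all(feat == 0 | feat == 1)) {
    bad <- which(!(feat == 0 | feat == 1) | is.na(feat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary cell at row %d, column '%s'",
                 bad[[1L]], colnames(feat)[bad[[2L]]]), call. = FALSE)
  }
  out <- dt[[length(nm)]]
  if (anyNA(out) || !all(out == 0 | out == 1)) {
    bad <- which(is.na(out) | !(out == 0 | out == 1))[1L]
    stop(sprintf("non-binary cell at row %d, column 'outcome'", bad),
         call. = FALSE)
  }
  as_cohort(feat, out)
}
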
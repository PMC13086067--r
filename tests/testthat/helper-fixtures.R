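# Small in-code fixtures shared across test files.

# A compact cohort with two planted effects; cheap enough for repeated fits.
small_cohort <- function(n = 400, m = 12, effects = c("2" = 1.2, "5" = 0.9),
                         seed = 42) {
  generate_cohort(generator_config(
    n_instances = n, n_features = m, planted_effects = effects,
    prevalence_shape = c(2, 6), seed = seed))
}

# A cohort whose outcome is a copy of feature "1": perfectly separable.
separable_cohort <- function(n = 100, seed = 1) {
  x1 <- withr::with_seed(seed, rbinom(n, 1L, 0.5))
  x2 <- withr::with_seed(seed + 1L, rbinom(n, 1L, 0.3))
  feats <- cbind("1" = x1, "2" = x2)
  attrnoise:::as_cohort(feats, x1)
}

# A cohort with no signal at all.
null_cohort <- function(n = 500, m = 8, seed = 9) {
  generate_cohort(generator_config(
    n_instances = n, n_features = m,
    planted_effects = setNames(numeric(0), character(0)),
    prevalence_shape = c(2, 6), seed = seed))
}

# Random binary matrix with labelled columns.
rand_binary <- function(n, m, p = 0.3, seed = 1) {
  X <- withr::with_seed(seed, matrix(rbinom(n * m, 1L, p), n, m))
  colnames(X) <- as.character(seq_len(m))
  X
}
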
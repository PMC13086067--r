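test_that("prevalence sampling follows the Beta prior and is reproducible", {
  cfg <- generator_config(n_instances = 100, n_features = 20000,
                          planted_effects = c("1" = 0.5),
                          prevalence_shape = c(1, 9), seed = 3)
  prev <- sample_prevalences(cfg)
  expect_length(prev, 20000)
  expect_true(all(prev >= 0.01 & prev < 1))
  expect_lt(abs(mean(prev) - 1 / 10), 0.02)
  expect_identical(prev, sample_prevalences(cfg))

  # flat untruncated prior: second moment matches the uniform distribution
  flat <- generator_config(n_instances = 100, n_features = 1e6,
                           planted_effects = c("1" = 0),
                           prevalence_shape = c(1, 1), min_prevalence = 0,
                           seed = 5)
  expect_equal(var(sample_prevalences(flat)), 1 / 12, tolerance = 1e-3)

  expect_error(generator_config(prevalence_shape = c(0, 1)), "positive")
})

test_that("generated cohorts are balanced, binary, and deterministic", {
  cfg <- generator_config(n_instances = 401, n_features = 10,
                          planted_effects = c("3" = 0.8),
                          case_fraction = 0.5, seed = 11)
  coh <- generate_cohort(cfg)
  expect_s3_class(coh, "cohort")
  expect_identical(dim(coh$features), c(401L, 10L))
  expect_true(all(coh$features %in% c(0L, 1L)))
  # quota: round-half-away-from-zero of 200.5 is 201 cases
  expect_identical(sum(coh$outcome == 1L), 201L)
  expect_identical(sum(coh$outcome == 0L), 200L)
  # bit-identical under the same config
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$features, coh2$features)
  expect_identical(coh$outcome, coh2$outcome)
})

test_that("planted labels must exist among the feature labels", {
  expect_error(
    generator_config(n_instances = 100, n_features = 5,
                     planted_effects = c("117" = 0.98)),
    "117")
})

test_that("a null cohort yields near-zero logistic coefficients", {
  coh <- null_cohort(n = 4000, m = 8)
  fit <- fit_model(coh, model_spec("logistic_regression"))
  se <- attrnoise:::coef_se(fit)[-1L]
  expect_true(all(abs(coef(fit)) < 4 * se))
})

test_that("an unpenalized logistic fit recovers a planted effect", {
  cfg <- generator_config(n_instances = 4000, n_features = 15,
                          planted_effects = c("3" = 1.0), seed = 21)
  coh <- generate_cohort(cfg)
  fit <- fit_model(coh, model_spec("logistic_regression"))
  se <- attrnoise:::coef_se(fit)[["3"]]
  expect_lt(abs(coef(fit)[["3"]] - 1.0), 3 * se)
})

test_that("column prevalences converge to the sampled prevalences", {
  cfg <- generator_config(n_instances = 1e5, n_features = 40,
                          planted_effects = c("1" = 1.0),
                          prevalence_shape = c(1, 9), seed = 8)
  coh <- generate_cohort(cfg)
  prev <- attr(coh, "prevalences")
  # case-control reweighting only touches the planted column
  free <- setdiff(colnames(coh$features), "1")
  expect_true(all(abs(colMeans(coh$features[, free]) - prev[free]) < 0.01))
})

test_that("cohort files round-trip exactly and malformed files are rejected", {
  coh <- small_cohort(n = 60, m = 6)
  for (ext in c(".csv", ".tsv", ".csv.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cohort(coh, path)
    back <- read_cohort(path)
    expect_identical(back$features, coh$features)
    expect_identical(back$outcome, coh$outcome)
    expect_identical(back$labels, coh$labels)
  }

  # a non-binary cell is named in the error
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  txt <- readLines(path)
  txt[3] <- sub("^([01]),", "2,", txt[3])
  writeLines(txt, path)
  expect_error(read_cohort(path), "row 2, column '1'")

  # duplicate feature labels
  txt <- readLines(path)
  txt[1] <- sub("^1,2", "1,1", txt[1])
  writeLines(txt, path)
  expect_error(read_cohort(path), "duplicate")

  # missing outcome column
  writeLines(c("a,b", "0,1"), path)
  expect_error(read_cohort(path), "outcome")
})
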
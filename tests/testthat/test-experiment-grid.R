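tiny_grid_config <- function(...) {
  grid_config(
    cohort = generator_config(n_instances = 240, n_features = 12,
                              planted_effects = c("2" = 1.3, "5" = 1.0),
                              seed = 99),
    models = "logistic_regression",
    proportions = c(0, 0.1, 0.2),
    folds = 2, seed = 17, ...)
}

test_that("the grid produces one noisy dataset per mechanism and proportion", {
  res <- suppressWarnings(run_grid(tiny_grid_config()))
  expect_identical(sum(res$manifest$proportion > 0), 3L * 2L)
  # every cell evaluated: 3 mechanisms x 3 levels x 1 model
  expect_identical(nrow(res$metrics), 9L)
  expect_identical(nrow(res$anova), 3L)
  # impacts: one value per feature per cell
  expect_identical(nrow(res$impacts), 9L * 12L)
  # per-cell seeds recorded for every noisy dataset
  expect_false(anyNA(res$manifest$injection_seed[res$manifest$proportion > 0]))
})

test_that("grid runs are end-to-end deterministic under a fixed master seed", {
  cfg <- tiny_grid_config()
  r1 <- suppressWarnings(run_grid(cfg))
  r2 <- suppressWarnings(run_grid(cfg))
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$impacts, r2$impacts)
  expect_identical(r1$anova, r2$anova)
})

test_that("a baseline-only grid has no noisy datasets and no ANOVA", {
  cfg <- grid_config(
    cohort = generator_config(n_instances = 240, n_features = 12,
                              planted_effects = c("2" = 1.3), seed = 99),
    models = "logistic_regression", proportions = 0, folds = 2, seed = 17)
  res <- suppressWarnings(run_grid(cfg))
  expect_identical(sum(res$manifest$proportion > 0), 0L)
  expect_null(res$anova)
  outdir <- withr::local_tempdir()
  files <- report(res, outdir, figures = FALSE)
  expect_false(any(grepl("percent_change", files)))
})

test_that("the report bundle contains the study tables and refuses partial results", {
  res <- suppressWarnings(run_grid(tiny_grid_config()))
  outdir <- withr::local_tempdir()
  files <- report(res, outdir, figures = TRUE)
  base <- basename(files)
  expect_true(all(c("metrics_by_noise.csv", "impact_scores.csv",
                    "percent_change.csv", "impact_dispersion.csv",
                    "rm_anova.csv", "manifest.json", "fig_metrics.png") %in% base))
  expect_true(any(grepl("^top\\d+_NCAR_logistic_regression", base)))
  # top tables have one row per requested feature and one column per level
  tk <- read.csv(file.path(outdir, grep("^top", base, value = TRUE)[1]),
                 check.names = FALSE)
  expect_identical(ncol(tk), 1L + 3L)

  partial <- res
  partial$metrics <- partial$metrics[partial$metrics$mechanism != "NAR", ]
  expect_error(report(partial, withr::local_tempdir()), "missing cells")
})

test_that("replicated grids aggregate metrics as mean and sd", {
  cfg <- grid_config(
    cohort = generator_config(n_instances = 200, n_features = 10,
                              planted_effects = c("2" = 1.2), seed = 31),
    mechanisms = "NCAR", models = "logistic_regression",
    proportions = c(0, 0.2), folds = 2, replicates = 2, seed = 5)
  res <- suppressWarnings(run_grid(cfg))
  expect_identical(sum(res$manifest$proportion > 0), 2L)
  # replicates draw different cohorts
  expect_false(identical(
    res$metrics$mean_auc[res$metrics$replicate == 1],
    res$metrics$mean_auc[res$metrics$replicate == 2]))
  outdir <- withr::local_tempdir()
  report(res, outdir, figures = FALSE)
  agg <- read.csv(file.path(outdir, "metrics_by_noise.csv"))
  expect_true(all(c("auc_sd", "accuracy_sd") %in% names(agg)))
  expect_identical(nrow(agg), 2L)
})

test_that("grid configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cohort:",
    "  n_instances: 300",
    "  n_features: 10",
    "  planted_effects:",
    "    '2': 1.1",
    "  seed: 4",
    "mechanisms: [NCAR, NNAR]",
    "proportions: [0.0, 0.1]",
    "models: [logistic_regression]",
    "folds: 2",
    "seed: 12"), path)
  cfg <- read_grid_config(path)
  expect_s3_class(cfg, "grid_config")
  expect_identical(cfg$mechanisms, c("NCAR", "NNAR"))
  expect_identical(cfg$cohort$n_instances, 300L)
  expect_identical(unlist(cfg$cohort$planted_effects), c("2" = 1.1))
})
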
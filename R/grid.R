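# Orchestration of the full mechanism x proportion x model experiment.

#' Configuration of a full noise-sensitivity grid
#'
#' @param cohort cohort source: a [generator_config()] (a fresh cohort is
#'   generated per replicate from a derived seed), a `cohort` object, or a
#'   path to a cohort file readable by [read_cohort()].
#' @param mechanisms subset of `c("NCAR", "NAR", "NNAR")`.
#' @param proportions ordered noise proportions; the clean baseline 0 is
#'   always included. Default `0, 0.05, ..., 0.30`.
#' @param models subset of the three supported algorithms.
#' @param replicates number of independent grid replicates (default 1).
#' @param folds cross-validation folds for the discrimination metrics.
#' @param changeable_fraction NAR changeable-feature fraction.
#' @param seed master seed; every cell seed is derived from it (see
#'   [derive_seed()]) and recorded in the result manifest.
#' @return an object of class `grid_config`.
#' @export
grid_config <- function(cohort = generator_config(),
                        mechanisms = c("NCAR", "NAR", "NNAR"),
                        proportions = seq(0, 0.30, by = 0.05),
                        models = c("logistic_regression", "linear_svm",
                                   "gradient_boosting"),
                        replicates = 1L,
                        folds = 5L,
                        changeable_fraction = 0.5,
                        seed = 1L) {
  mechanisms <- match.arg(mechanisms, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  proportions <- sort(unique(c(0, as.numeric(proportions))))
  if (any(proportions < 0 | proportions >= 1)) {
    stop("proportions must lie in [0, 1)", call. = FALSE)
  }
  if (!is_count(replicates)) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  ok_source <- inherits(cohort, "generator_config") ||
    inherits(cohort, "cohort") ||
    (is.character(cohort) && length(cohort) == 1L)
  if (!ok_source) {
    stop("cohort must be a generator_config, a cohort, or a file path",
         call. = FALSE)
  }
  structure(
    list(cohort = cohort, mechanisms = mechanisms,
         proportions = proportions, models = models,
         replicates = as.integer(replicates), folds = as.integer(folds),
         changeable_fraction = changeable_fraction, seed = as.integer(seed)),
    class = "grid_config"
  )
}

#' Read a grid configuration from YAML or JSON
#'
#' The file mirrors the [grid_config()] argument names; a `cohort` block
#' mirrors [generator_config()] (or is a file path string).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `grid_config`.
#' @export
read_grid_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$cohort) && is.list(cfg$cohort)) {
    cfg$cohort <- do.call(generator_config, cfg$cohort)
  }
  do.call(grid_config, cfg)
}

resolve_cohort <- function(source, replicate_seed) {
  if (inherits(source, "cohort")) return(source)
  if (is.character(source)) return(read_cohort(source))
  gc <- source
  gc$seed <- replicate_seed
  generate_cohort(gc)
}

#' Run the full noise-sensitivity experiment grid
#'
#' For each replicate: one clean baseline cohort plus one noisy dataset per
#' (mechanism, nonzero proportion); every requested model is fitted and
#' cross-validated on every dataset, per-feature impact scores are computed
#' from a full-data refit (one value per dataset, as in single-dataset
#' reporting), and a repeated-measures ANOVA across proportions is run per
#' (mechanism, model). Noise is applied to the full cohort before the
#' cross-validation split; fold assignments are shared across all datasets
#' of a replicate so that noise is the only varying factor.
#'
#' @param config a [grid_config()].
#' @return an object of class `grid_result`: list with data frames
#'   `metrics` (mean AUC/accuracy per cell), `fold_metrics` (per fold),
#'   `impacts` (long: replicate, mechanism, model, proportion, feature,
#'   impact), `anova` (per mechanism x model), `manifest` (all derived
#'   seeds) and the `config`.
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "grid_config"))
  mech_index <- c(NCAR = 1L, NAR = 2L, NNAR = 3L)
  metrics <- list(); fold_metrics <- list(); impacts <- list()
  anova_rows <- list(); manifest <- list()

  for (r in seq_len(config$replicates)) {
    cohort_seed <- derive_seed(config$seed, 10L, r)
    fold_seed <- derive_seed(config$seed, 20L, r)
    cohort <- resolve_cohort(config$cohort, cohort_seed)
    datasets <- list(list(mechanism = "baseline", proportion = 0,
                          features = cohort$features, seed = NA_integer_))
    for (mech in config$mechanisms) {
      for (pi in which(config$proportions > 0)) {
        p <- config$proportions[pi]
        cell_seed <- derive_seed(config$seed, 30L, mech_index[[mech]], pi, r)
        spec <- noise_spec(mech, p, seed = cell_seed,
                           changeable_fraction = config$changeable_fraction)
        inj <- inject_noise(cohort$features, spec)
        datasets[[length(datasets) + 1L]] <-
          list(mechanism = mech, proportion = p, features = inj$noisy,
               seed = cell_seed)
      }
    }
    manifest[[r]] <- data.frame(
      replicate = r,
      mechanism = vapply(datasets, `[[`, "", "mechanism"),
      proportion = vapply(datasets, `[[`, 0, "proportion"),
      injection_seed = vapply(datasets, `[[`, NA_integer_, "seed"),
      cohort_seed = cohort_seed, fold_seed = fold_seed
    )

    for (ds in datasets) {
      dcohort <- cohort
      dcohort$features <- ds$features
      for (model in config$models) {
        mspec <- model_spec(model, seed = derive_seed(config$seed, 40L, r))
        ev <- evaluate(dcohort, mspec, folds = config$folds, seed = fold_seed)
        full_fit <- fit_model(dcohort, mspec)
        imp <- impact_scores(full_fit, ds$features)
        # the clean baseline belongs to every mechanism's panel
        mechs <- if (ds$mechanism == "baseline") config$mechanisms else ds$mechanism
        for (mech in mechs) {
          metrics[[length(metrics) + 1L]] <- data.frame(
            replicate = r, mechanism = mech, proportion = ds$proportion,
            model = model, mean_auc = ev$mean_auc,
            mean_accuracy = ev$mean_accuracy
          )
          fold_metrics[[length(fold_metrics) + 1L]] <- data.frame(
            replicate = r, mechanism = mech, proportion = ds$proportion,
            model = model, ev$folds
          )
          impacts[[length(impacts) + 1L]] <- data.frame(
            replicate = r, mechanism = mech, proportion = ds$proportion,
            model = model, feature = names(imp), impact = unname(imp)
          )
        }
      }
    }
  }

  metrics <- do.call(rbind, metrics)
  fold_metrics <- do.call(rbind, fold_metrics)
  impacts <- do.call(rbind, impacts)
  manifest <- do.call(rbind, manifest)

  result <- structure(
    list(metrics = metrics, fold_metrics = fold_metrics, impacts = impacts,
         anova = NULL, manifest = manifest, config = config),
    class = "grid_result"
  )

  if (length(config$proportions) > 1L) {
    for (r in seq_len(config$replicates)) {
      for (mech in config$mechanisms) {
        for (model in config$models) {
          it <- grid_impact_table(result, mech, model, replicate = r)
          a <- rm_anova(it)
          anova_rows[[length(anova_rows) + 1L]] <- data.frame(
            replicate = r, mechanism = mech, model = model,
            F = a$F, df_treatment = a$df_treatment, df_error = a$df_error,
            p_value = a$p_value, gg_epsilon = a$gg_epsilon
          )
        }
      }
    }
    result$anova <- do.call(rbind, anova_rows)
  }
  result
}

#' Extract one (mechanism, model) impact table from a grid result
#'
#' @param result a `grid_result`.
#' @param mechanism,model,replicate the cell to extract.
#' @return an [impact_table()] (features x all noise levels).
#' @export
grid_impact_table <- function(result, mechanism, model, replicate = 1L) {
  stopifnot(inherits(result, "grid_result"))
  sub <- result$impacts[result$impacts$mechanism == mechanism &
                          result$impacts$model == model &
                          result$impacts$replicate == replicate, ]
  if (!nrow(sub)) {
    stop("no impacts for the requested cell", call. = FALSE)
  }
  levels <- sort(unique(sub$proportion))
  feats <- unique(sub$feature)
  scores <- matrix(NA_real_, length(feats), length(levels),
                   dimnames = list(feats, format_level(levels)))
  for (i in seq_along(levels)) {
    s <- sub[sub$proportion == levels[i], ]
    scores[s$feature, i] <- s$impact
  }
  impact_table(scores, levels, mechanism = mechanism, model = model)
}

#' @export
print.grid_result <- function(x, ...) {
  n_noisy <- sum(x$manifest$proportion > 0)
  cat(sprintf("<grid_result> %d noisy datasets, %d model evaluations\n",
              n_noisy, nrow(x$metrics)))
  invisible(x)
}

#' Write the report bundle of a grid run
#'
#' Writes, under `outdir`: the metrics-versus-noise table and figure, the
#' percent-change table and per-mechanism figure, top-k impact tables per
#' (mechanism, model), the mean/variance dispersion trajectories, the
#' RM-ANOVA summary, and a JSON manifest of every derived seed. With more
#' than one replicate, metrics are aggregated as mean and sd across
#' replicates. Refuses a partial result (missing grid cells).
#'
#' @param result a `grid_result`.
#' @param outdir output directory (created if needed).
#' @param top_k rows in the top-impact tables (default 10, capped at the
#'   feature count).
#' @param figures write PNG figures (default TRUE).
#' @return invisibly, the vector of files written.
#' @export
report <- function(result, outdir, top_k = 10L, figures = TRUE) {
  stopifnot(inherits(result, "grid_result"))
  cfg <- result$config
  expected <- expand.grid(mechanism = cfg$mechanisms,
                          proportion = cfg$proportions,
                          model = cfg$models, replicate = seq_len(cfg$replicates),
                          stringsAsFactors = FALSE)
  have <- result$metrics[c("mechanism", "proportion", "model", "replicate")]
  missing <- !apply(expected, 1L, function(row) {
    any(have$mechanism == row[["mechanism"]] &
          have$proportion == as.numeric(row[["proportion"]]) &
          have$model == row[["model"]] &
          have$replicate == as.integer(row[["replicate"]]))
  })
  if (any(missing)) {
    stop("partial grid result; missing cells:\n",
         paste(utils::capture.output(print(expected[missing, ])),
               collapse = "\n"), call. = FALSE)
  }

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, name)
    data.table::fwrite(df, path)
    files <<- c(files, path)
  }

  agg <- stats::aggregate(cbind(mean_auc, mean_accuracy) ~
                            mechanism + proportion + model,
                          data = result$metrics, FUN = mean)
  names(agg)[names(agg) == "mean_auc"] <- "auc"
  names(agg)[names(agg) == "mean_accuracy"] <- "accuracy"
  if (cfg$replicates > 1L) {
    sdagg <- stats::aggregate(cbind(mean_auc, mean_accuracy) ~
                                mechanism + proportion + model,
                              data = result$metrics, FUN = sd)
    agg$auc_sd <- sdagg$mean_auc
    agg$accuracy_sd <- sdagg$mean_accuracy
  }
  put(agg, "metrics_by_noise.csv")
  put(result$fold_metrics, "fold_metrics.csv")
  put(result$impacts, "impact_scores.csv")

  pc_rows <- list(); disp_rows <- list(); top_written <- FALSE
  multi_level <- length(cfg$proportions) > 1L
  for (mech in cfg$mechanisms) {
    for (model in cfg$models) {
      for (r in seq_len(cfg$replicates)) {
        it <- grid_impact_table(result, mech, model, replicate = r)
        disp <- dispersion_trajectory(it)
        disp_rows[[length(disp_rows) + 1L]] <-
          data.frame(replicate = r, mechanism = mech, model = model, disp)
        if (multi_level) {
          pc <- percent_change(it)
          pc_rows[[length(pc_rows) + 1L]] <- data.frame(
            replicate = r, mechanism = mech, model = model,
            feature = rownames(pc), pc, row.names = NULL, check.names = FALSE)
          tk <- top_k_table(it, min(top_k, nrow(it$scores)))
          put(tk, sprintf("top%d_%s_%s_rep%d.csv", min(top_k, nrow(it$scores)),
                          mech, model, r))
          top_written <- TRUE
        }
      }
    }
  }
  put(do.call(rbind, disp_rows), "impact_dispersion.csv")
  if (multi_level) {
    put(do.call(rbind, pc_rows), "percent_change.csv")
    put(result$anova, "rm_anova.csv")
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass_config(cfg), datasets = result$manifest),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)

  if (figures) {
    fig <- file.path(outdir, "fig_metrics.png")
    grDevices::png(fig, width = 1600, height = 900, res = 150)
    print(plot_metric_trajectories(result))
    grDevices::dev.off()
    files <- c(files, fig)
    if (multi_level) {
      for (mech in cfg$mechanisms) {
        fig <- file.path(outdir, sprintf("fig_percent_change_%s.png", mech))
        grDevices::png(fig, width = 1600, height = 700, res = 150)
        print(plot_percent_change(result, mech, top_k = min(top_k, 10L)))
        grDevices::dev.off()
        files <- c(files, fig)
      }
    }
  }
  invisible(files)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  if (inherits(out$cohort, "generator_config")) {
    out$cohort <- unclass(out$cohort)
    out$cohort$planted_effects <- as.list(out$cohort$planted_effects)
  } else if (inherits(out$cohort, "cohort")) {
    out$cohort <- sprintf("<in-memory cohort: %d x %d>",
                          nrow(out$cohort$features), ncol(out$cohort$features))
  }
  out
}
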
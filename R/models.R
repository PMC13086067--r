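# Classifier harness: logistic regression, linear SVM, gradient boosting.
#
# Every fitted handle exposes one thing downstream code relies on: a decision
# score per instance on an additive scale (log-odds for logistic and
# boosting, signed margin for the SVM). Accuracy is always taken at the
# score-zero threshold (probability 0.5).

#' Specification of a classifier
#'
#' @param algorithm one of `"logistic_regression"`, `"linear_svm"`,
#'   `"gradient_boosting"`.
#' @param hyperparameters named list overriding the per-algorithm defaults:
#'   logistic regression is unpenalized (`maxit = 100`); the linear SVM uses
#'   hinge loss with unit cost (`cost = 1`) on unscaled inputs; gradient
#'   boosting uses `nrounds = 100`, `max_depth = 3`, `eta = 0.1` with a
#'   logistic objective on a single thread.
#' @param seed integer seed (gradient boosting only; the other two fits are
#'   deterministic).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("logistic_regression", "linear_svm",
                                     "gradient_boosting"),
                       hyperparameters = list(),
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    logistic_regression = list(maxit = 100L),
    linear_svm = list(cost = 1),
    gradient_boosting = list(nrounds = 100L, max_depth = 3L, eta = 0.1)
  )
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameters for ", algorithm, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(algorithm = algorithm,
         hyperparameters = modifyList(defaults, hyperparameters),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Fit a classifier to a cohort
#'
#' @param cohort a `cohort` (binary features, binary outcome, both classes
#'   present).
#' @param spec a [model_spec()].
#' @return an object of class `attrnoise_fit` exposing [predict_scores()]
#'   and, for the two linear models, `coef()` (per-feature weights, no
#'   intercept).
#' @export
fit_model <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "model_spec"))
  X <- cohort$features
  y <- cohort$outcome
  assert_binary_matrix(X)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; cannot fit a classifier", call. = FALSE)
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    logistic_regression = {
      Xd <- cbind("(Intercept)" = 1, X)
      g <- glm.fit(Xd, y, family = binomial(),
                   control = list(maxit = hp$maxit))
      cf <- g$coefficients
      cf[is.na(cf)] <- 0  # aliased (e.g. constant) columns contribute nothing
      list(w = cf[-1L], b = cf[[1L]],
           qr_R = g$R, qr_pivot = g$qr$pivot, rank = g$rank,
           converged = g$converged)
    },
    linear_svm = {
      sv <- kernlab::ksvm(x = X, y = factor(y, levels = c(0L, 1L)),
                          kernel = kernlab::vanilladot(),
                          C = hp$cost, scaled = FALSE)
      w <- colSums(kernlab::coef(sv)[[1L]] *
                     X[kernlab::alphaindex(sv)[[1L]], , drop = FALSE])
      # kernlab decision value = x.w - b, oriented so the second factor
      # level (the cases) scores positive.
      list(w = w, b = -kernlab::b(sv))
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      booster <- withr::with_seed(spec$seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, eta = hp$eta,
                      nthread = 1L),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      ))
      list(booster = booster)
    }
  )
  structure(
    c(fit, list(algorithm = spec$algorithm, spec = spec,
                labels = cohort$labels)),
    class = "attrnoise_fit"
  )
}

#' Decision scores of a fitted model
#'
#' Returns the per-instance decision score on the model's additive scale:
#' the linear predictor (log-odds) for logistic regression, the signed
#' margin for the SVM, and the untransformed boosting margin (log-odds) for
#' gradient boosting. Positive scores classify as case.
#'
#' @param fit an `attrnoise_fit`.
#' @param features binary matrix with the same columns as the training data.
#' @return numeric vector of length `nrow(features)`.
#' @export
predict_scores <- function(fit, features) {
  stopifnot(inherits(fit, "attrnoise_fit"))
  if (ncol(features) != length(fit$labels)) {
    stop("feature matrix has the wrong number of columns", call. = FALSE)
  }
  switch(fit$algorithm,
    logistic_regression = ,
    linear_svm = drop(features %*% fit$w) + fit$b,
    gradient_boosting = predict(fit$booster, xgboost::xgb.DMatrix(features),
                                outputmargin = TRUE)
  )
}

#' @export
coef.attrnoise_fit <- function(object, ...) {
  if (object$algorithm == "gradient_boosting") {
    stop("gradient boosting has no coefficient vector; use impact_scores()",
         call. = FALSE)
  }
  setNames(as.numeric(object$w), object$labels)
}

# Standard errors of the logistic coefficients, from the (pivoted) R factor
# of the weighted design that glm.fit already computed.
coef_se <- function(fit) {
  stopifnot(inherits(fit, "attrnoise_fit"),
            fit$algorithm == "logistic_regression")
  p <- fit$rank
  R <- fit$qr_R[seq_len(p), seq_len(p), drop = FALSE]
  cov_pivoted <- chol2inv(R)
  se <- rep(NA_real_, length(fit$labels) + 1L)
  se[fit$qr_pivot[seq_len(p)]] <- sqrt(diag(cov_pivoted))
  setNames(se, c("(Intercept)", fit$labels))
}

# Stratified fold assignment: within each class, a seeded permutation of a
# balanced fold sequence.
stratified_folds <- function(y, folds, seed) {
  if (min(table(y)) < folds) {
    stop("stratification impossible: a class has fewer members than folds",
         call. = FALSE)
  }
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

#' Cross-validated discrimination metrics
#'
#' Stratified k-fold cross-validation: the model is refitted on each
#' training split and scored on the held-out fold. AUC is the area under the
#' ROC curve of the held-out scores; accuracy is taken at the zero decision
#' threshold (probability 0.5).
#'
#' @param cohort a `cohort`.
#' @param spec a [model_spec()].
#' @param folds number of folds (>= 2; default 5).
#' @param seed seed for the fold assignment.
#' @return an object of class `eval_result`: list with `folds` (data frame
#'   of per-fold `auc` and `accuracy`), `mean_auc`, `mean_accuracy`,
#'   `fold_seed` and `algorithm`.
#' @export
evaluate <- function(cohort, spec, folds = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (!is_count(folds, min = 2)) {
    stop("folds must be an integer >= 2", call. = FALSE)
  }
  y <- cohort$outcome
  assign <- stratified_folds(y, folds, seed)
  per_fold <- lapply(seq_len(folds), function(k) {
    train <- subset_cohort(cohort, assign != k)
    test_idx <- which(assign == k)
    fit <- fit_model(train, spec)
    s <- predict_scores(fit, cohort$features[test_idx, , drop = FALSE])
    yt <- y[test_idx]
    a <- as.numeric(pROC::auc(response = yt, predictor = s,
                              levels = c(0L, 1L), direction = "<",
                              quiet = TRUE))
    data.frame(fold = k, auc = a, accuracy = mean((s > 0) == (yt == 1L)))
  })
  tab <- do.call(rbind, per_fold)
  structure(
    list(folds = tab,
         mean_auc = mean(tab$auc),
         mean_accuracy = mean(tab$accuracy),
         fold_seed = as.integer(seed),
         algorithm = spec$algorithm),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: mean AUC %.4f, mean accuracy %.4f over %d folds\n",
              x$algorithm, x$mean_auc, x$mean_accuracy, nrow(x$folds)))
  invisible(x)
}
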
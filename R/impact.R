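# Per-feature impact scores and their stability summaries.
#
# The impact of feature j is the mean change in the model's decision score
# when x_j is toggled: mean_i [ score(x_i with x_ij = 1) -
# score(x_i with x_ij = 0) ], on the log-odds / margin scale. For a linear
# model this equals the coefficient exactly; for tree ensembles it averages
# the score contrast over the observed covariate patterns, generalising the
# coefficient to nonlinear models.

# ---- gradient-boosting tree walk --------------------------------------

# Parse the booster into one small table per tree: node-indexed vectors of
# split feature (NA at leaves), split point, child indices and leaf values.
parse_booster_trees <- function(booster, feature_names) {
  dump <- xgboost::xgb.model.dt.tree(model = booster)
  dump <- as.data.frame(dump)
  lapply(split(dump, dump$Tree), function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    node_of <- function(id) match(id, tr$ID)
    list(
      feat = match(tr$Feature, feature_names),   # NA for leaves
      split = tr$Split,
      yes = node_of(tr$Yes),
      no = node_of(tr$No),
      value = tr$Gain,                           # leaf output where leaf
      is_leaf = tr$Feature == "Leaf"
    )
  })
}

# Vectorized evaluation of one parsed tree, optionally forcing one feature
# column to a constant (the toggle). No missing values, so the Missing
# branch never applies.
eval_tree <- function(tree, X, override_col = 0L, override_val = 0) {
  n <- nrow(X)
  out <- numeric(n)
  recurse <- function(node, rows) {
    if (!length(rows)) return(invisible(NULL))
    if (tree$is_leaf[node]) {
      out[rows] <<- tree$value[node]
      return(invisible(NULL))
    }
    f <- tree$feat[node]
    xv <- if (f == override_col) rep.int(override_val, length(rows))
          else X[rows, f]
    go_yes <- xv < tree$split[node]
    recurse(tree$yes[node], rows[go_yes])
    recurse(tree$no[node], rows[!go_yes])
  }
  recurse(1L, seq_len(n))
  out
}

impact_gbm <- function(fit, features) {
  m <- ncol(features)
  out <- numeric(m)
  trees <- fit$trees
  if (is.null(trees)) {
    trees <- parse_booster_trees(fit$booster, colnames(features))
  }
  uses <- lapply(trees, function(tr) unique(tr$feat[!tree_na(tr)]))
  by_feature <- vector("list", m)
  for (t in seq_along(trees)) {
    for (j in uses[[t]]) {
      by_feature[[j]] <- c(by_feature[[j]], t)
    }
  }
  for (j in seq_len(m)) {
    trees_j <- by_feature[[j]]
    if (is.null(trees_j)) next  # feature never split on: impact exactly 0
    diff <- numeric(nrow(features))
    for (t in trees_j) {
      diff <- diff + eval_tree(trees[[t]], features, j, 1) -
        eval_tree(trees[[t]], features, j, 0)
    }
    out[j] <- mean(diff)
  }
  names(out) <- colnames(features)
  out
}

tree_na <- function(tr) is.na(tr$feat)

# ---- impact scores ----------------------------------------------------

#' Model-agnostic per-feature impact scores
#'
#' For every feature, the mean over instances of the difference in decision
#' score between the feature forced to 1 and forced to 0. Equals the
#' coefficient for the two linear models; for gradient boosting only the
#' trees that split on the toggled feature contribute, which the
#' implementation exploits (the result is identical to exhaustively
#' re-scoring every instance with the feature toggled both ways).
#'
#' @param fit an `attrnoise_fit`.
#' @param features binary matrix over which the toggle mean is taken
#'   (normally the training features).
#' @return numeric vector named by feature label.
#' @export
impact_scores <- function(fit, features) {
  stopifnot(inherits(fit, "attrnoise_fit"))
  assert_binary_matrix(features)
  if (fit$algorithm == "gradient_boosting") {
    return(impact_gbm(fit, features))
  }
  m <- ncol(features)
  out <- numeric(m)
  W <- features
  storage.mode(W) <- "double"  # one coercion instead of one per toggle
  for (j in seq_len(m)) {
    orig <- W[, j]
    W[, j] <- 1L
    s1 <- predict_scores(fit, W)
    W[, j] <- 0L
    s0 <- predict_scores(fit, W)
    W[, j] <- orig
    out[j] <- mean(s1 - s0)
  }
  names(out) <- colnames(features)
  out
}

# ---- impact tables ----------------------------------------------------

#' Impact table across noise levels
#'
#' Container for the per-feature impact scores of one (mechanism, model)
#' experiment: one column per noise proportion, the clean baseline included.
#'
#' @param scores numeric matrix, rows = features, columns = noise levels.
#' @param levels numeric vector of noise proportions, one per column;
#'   must contain 0 (the baseline).
#' @param mechanism,model,seed metadata recorded on the table.
#' @return an object of class `impact_table`.
#' @export
impact_table <- function(scores, levels, mechanism = NA_character_,
                         model = NA_character_, seed = NA_integer_) {
  scores <- as.matrix(scores)
  if (length(levels) != ncol(scores)) {
    stop("one level per score column required", call. = FALSE)
  }
  if (!any(levels == 0)) {
    stop("impact table must include the clean baseline (level 0)",
         call. = FALSE)
  }
  if (is.null(rownames(scores))) {
    stop("score rows must be named by feature label", call. = FALSE)
  }
  colnames(scores) <- format_level(levels)
  structure(
    list(scores = scores, levels = as.numeric(levels),
         mechanism = mechanism, model = model, seed = seed),
    class = "impact_table"
  )
}

format_level <- function(p) sprintf("p%02d", round(100 * p))

#' @export
print.impact_table <- function(x, ...) {
  cat(sprintf("<impact_table> %d features x %d levels (%s, %s)\n",
              nrow(x$scores), ncol(x$scores), x$mechanism, x$model))
  print(head(x$scores))
  invisible(x)
}

#' Percent change of impact scores versus the clean baseline
#'
#' `100 * (impact(p) - impact(0)) / |impact(0)|` per feature and level.
#' Features whose baseline magnitude falls below `eps` are reported as `NA`
#' rather than blowing up to infinity.
#'
#' @param impact an [impact_table()].
#' @param eps floor on the baseline magnitude (default `1e-8`).
#' @return numeric matrix with the same shape as the score matrix.
#' @export
percent_change <- function(impact, eps = 1e-8) {
  stopifnot(inherits(impact, "impact_table"))
  base <- impact$scores[, impact$levels == 0, drop = TRUE]
  out <- 100 * sweep(sweep(impact$scores, 1, base, "-"), 1, abs(base), "/")
  out[abs(base) < eps, ] <- NA_real_
  out
}

#' Top-k features by baseline impact magnitude
#'
#' The k features with the largest clean-baseline `|impact|`, ordered
#' descending (ties broken by feature label), with their scores at every
#' noise level -- the layout of a "largest impact scores versus noise"
#' table.
#'
#' @param impact an [impact_table()].
#' @param k number of rows (<= number of features).
#' @return data frame: `feature` column plus one column per noise level.
#' @export
top_k_table <- function(impact, k) {
  stopifnot(inherits(impact, "impact_table"))
  if (!is_count(k, min = 1) || k > nrow(impact$scores)) {
    stop("k must be a positive count no larger than the number of features",
         call. = FALSE)
  }
  base <- impact$scores[, impact$levels == 0, drop = TRUE]
  ord <- order(-abs(base), rownames(impact$scores))[seq_len(k)]
  data.frame(feature = rownames(impact$scores)[ord],
             impact$scores[ord, , drop = FALSE],
             row.names = NULL, check.names = FALSE)
}

#' Mean and variance of impact scores per noise level
#'
#' The dispersion trajectory behind the variance-collapse finding: for each
#' noise level, the sample mean, mean magnitude and sample variance
#' (denominator n - 1) of the impact column across features.
#'
#' @param impact an [impact_table()] with at least two features.
#' @return data frame with columns `proportion`, `mean`, `mean_abs`,
#'   `variance`.
#' @export
dispersion_trajectory <- function(impact) {
  stopifnot(inherits(impact, "impact_table"))
  if (nrow(impact$scores) < 2L) {
    stop("dispersion requires at least two features", call. = FALSE)
  }
  data.frame(
    proportion = impact$levels,
    mean = colMeans(impact$scores),
    mean_abs = colMeans(abs(impact$scores)),
    variance = apply(impact$scores, 2, var),
    row.names = NULL
  )
}
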
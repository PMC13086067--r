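# One-way repeated-measures ANOVA across noise proportions.
#
# Subjects are the features, the within-subject factor is the noise
# proportion; one analysis per (mechanism, model) impact table. The F test
# is the classical decomposition SS_total = SS_subjects + SS_treatment +
# SS_error with F = MS_treatment / MS_error on (k - 1, (k - 1)(s - 1))
# degrees of freedom, reported uncorrected. Greenhouse-Geisser epsilon is
# computed as a sphericity diagnostic but never applied.

#' Repeated-measures ANOVA on an impact table
#'
#' @param impact an [impact_table()], or a numeric matrix with rows =
#'   subjects (features) and columns = within-subject levels (noise
#'   proportions). At least two subjects and two levels; no missing cells.
#' @return an object of class `rm_anova_result`: list with `F` statistic,
#'   `df_treatment`, `df_error`, `p_value`, and `gg_epsilon` (diagnostic
#'   only -- the p value is uncorrected).
#' @examples
#' m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("f", 1:4), NULL))
#' rm_anova(m)
#' @export
rm_anova <- function(impact) {
  scores <- if (inherits(impact, "impact_table")) impact$scores else as.matrix(impact)
  if (anyNA(scores)) {
    stop("impact table has missing cells", call. = FALSE)
  }
  s <- nrow(scores); k <- ncol(scores)
  if (s < 2L || k < 2L) {
    stop("repeated-measures ANOVA needs >= 2 subjects and >= 2 levels",
         call. = FALSE)
  }
  if (max(scores) - min(scores) == 0) {
    # no variation at all: the decomposition is identically zero
    return(structure(
      list(F = 0, df_treatment = as.integer(k - 1L),
           df_error = as.integer((k - 1L) * (s - 1L)), p_value = 1,
           gg_epsilon = NA_real_),
      class = "rm_anova_result"
    ))
  }
  long <- data.frame(
    score = as.vector(scores),
    level = factor(rep(seq_len(k), each = s)),
    subject = factor(rep(seq_len(s), times = k))
  )
  fit <- aov(score ~ level + Error(subject), data = long)
  within <- summary(fit)[["Error: Within"]][[1L]]
  ss_treat <- within["level", "Sum Sq"]
  ss_error <- within["Residuals", "Sum Sq"]
  df1 <- within["level", "Df"]
  df2 <- within["Residuals", "Df"]
  if (ss_error <= 0) {
    # degenerate tables: no within-subject variation left
    F_stat <- if (ss_treat <= 0) 0 else Inf
    p <- if (ss_treat <= 0) 1 else 0
  } else {
    F_stat <- within["level", "F value"]
    p <- within["level", "Pr(>F)"]
  }
  structure(
    list(F = F_stat, df_treatment = as.integer(df1),
         df_error = as.integer(df2), p_value = p,
         gg_epsilon = gg_epsilon(scores)),
    class = "rm_anova_result"
  )
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix.
gg_epsilon <- function(scores) {
  k <- ncol(scores)
  S <- stats::cov(scores)
  dbar <- mean(diag(S))
  sbar <- mean(S)
  rowbar <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowbar^2) + k^2 * sbar^2)
  if (den <= 0) return(NA_real_)
  num / den
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.4f, p = %.4g (GG epsilon %.3f)\n",
              x$df_treatment, x$df_error, x$F, x$p_value, x$gg_epsilon))
  invisible(x)
}
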
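# Figures for the grid report.

#' Discrimination metrics versus noise proportion
#'
#' Line panel of mean cross-validated AUC and accuracy against noise
#' proportion, faceted by metric and mechanism, coloured by model --
#' replicate means when the grid was replicated.
#'
#' @param result a `grid_result`.
#' @return a ggplot object.
#' @export
plot_metric_trajectories <- function(result) {
  stopifnot(inherits(result, "grid_result"))
  agg <- stats::aggregate(cbind(mean_auc, mean_accuracy) ~
                            mechanism + proportion + model,
                          data = result$metrics, FUN = mean)
  long <- rbind(
    data.frame(agg[c("mechanism", "proportion", "model")],
               metric = "AUC", value = agg$mean_auc),
    data.frame(agg[c("mechanism", "proportion", "model")],
               metric = "Accuracy", value = agg$mean_accuracy)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = proportion, y = value,
                                     colour = model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_grid(metric ~ mechanism, scales = "free_y") +
    ggplot2::labs(x = "noise proportion", y = NULL, colour = NULL) +
    ggplot2::theme_bw()
}

#' Percent change of the top baseline impacts versus noise proportion
#'
#' For one mechanism: per-feature percent change (relative to the clean
#' baseline) of the `top_k` features with the largest baseline impact
#' magnitude, one line per feature, faceted by model. Replicate 1 is shown.
#'
#' @param result a `grid_result`.
#' @param mechanism which mechanism panel to draw.
#' @param top_k number of features to trace (default 10).
#' @return a ggplot object.
#' @export
plot_percent_change <- function(result, mechanism, top_k = 10L) {
  stopifnot(inherits(result, "grid_result"))
  rows <- list()
  for (model in result$config$models) {
    it <- grid_impact_table(result, mechanism, model, replicate = 1L)
    base <- it$scores[, it$levels == 0]
    keep <- order(-abs(base), rownames(it$scores))[seq_len(min(top_k, nrow(it$scores)))]
    pc <- percent_change(it)[keep, , drop = FALSE]
    for (i in seq_len(nrow(pc))) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, feature = rownames(pc)[i],
        proportion = it$levels, change = unname(pc[i, ]))
    }
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = proportion, y = change,
                                   group = feature,
                                   colour = feature)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(title = mechanism, x = "noise proportion",
                  y = "impact change vs baseline (%)", colour = "feature") +
    ggplot2::theme_bw()
}
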
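#' Plot methods for ERRmiR result objects
#'
#' `autoplot()` methods return ggplot objects: the ROC curve for an
#' evaluation report, the appearance-frequency distribution for a GA
#' frequency table, per-sample quartile plots contrasting raw expression
#' and ratio features for a stability report, and the train/validation
#' curves for a learning curve.
#'
#' @param object The result object.
#' @param ... Unused.
#' @name errmir_autoplot
NULL

#' @rdname errmir_autoplot
#' @export
autoplot.errmir_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2b6a99", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname errmir_autoplot
#' @param top_n Show only the `top_n` most frequent features.
#' @export
autoplot.errmir_freq <- function(object, top_n = 30, ...) {
  df <- head(as_tibble(object), top_n)
  df$feature_id <- factor(df$feature_id, levels = rev(df$feature_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$feature_id)) +
    ggplot2::geom_col(fill = "#2b6a99") +
    ggplot2::labs(
      x = sprintf("Appearances in %d GA optimal subsets",
                  attr(object, "n_repeats")),
      y = NULL, title = "ERRmiR feature selection frequency") +
    ggplot2::theme_minimal()
}

#' @rdname errmir_autoplot
#' @export
autoplot.errmir_stability <- function(object, ...) {
  df <- object$sample_quartiles
  df$type <- factor(df$type, levels = c("raw", "errmir"),
                    labels = c("log2 miRNA expression", "log2 ERRmiR ratio"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$median,
                                   colour = .data$batch)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                          ymax = .data$q75), size = 0.2) +
    ggplot2::facet_wrap(~type, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Per-sample quartiles",
                  title = "Cross-batch stability: raw expression vs ratio features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname errmir_autoplot
#' @export
autoplot.errmir_learning_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("train_score", "cv_score"),
                            names_to = "curve", values_to = "score")
  df$curve <- factor(df$curve, levels = c("train_score", "cv_score"),
                     labels = c("training", "cross-validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$score,
                                   colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Training-set size", y = "AUC", colour = NULL,
                  title = "Learning curve") +
    ggplot2::theme_minimal()
}
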
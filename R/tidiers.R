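# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a cross-validation fit
#'
#' One row per fold, class and metric: columns `fold`, `class`, `metric`,
#' `value`.
#'
#' @param x A `stage_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.stage_cv <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_folds), function(f) {
    pc <- x$fold_metrics[[f]]$per_class
    pc |>
      dplyr::select("class", "accuracy", "precision", "recall",
                    "specificity", "f1") |>
      tidyr::pivot_longer(-"class", names_to = "metric",
                          values_to = "value") |>
      dplyr::mutate(fold = f, .before = 1)
  })
}

#' One-row summary of a cross-validation fit
#'
#' @param x A `stage_cv`.
#' @param ... Unused.
#' @return Tibble with model, sizes, fold-mean and pooled accuracy, macro
#'   precision/recall/F1/specificity (pooled) and macro AUC.
#' @export
glance.stage_cv <- function(x, ...) {
  mp <- x$metrics_pooled$macro
  tibble::tibble(model = x$model, n = x$n, n_folds = x$n_folds,
                 accuracy_mean = x$accuracy_mean,
                 accuracy_pooled = x$accuracy_pooled,
                 macro_precision = mp[["precision"]],
                 macro_recall = mp[["recall"]],
                 macro_f1 = mp[["f1"]],
                 macro_specificity = mp[["specificity"]],
                 macro_auc = x$roc$macro_auc)
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with `actual`, `predicted`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame.table(unclass(x), responseName = "n")
  tibble::tibble(actual = as.character(df$actual),
                 predicted = as.character(df$predicted),
                 n = as.integer(df$n))
}

#' Tidy a metrics report
#'
#' @param x A `stage_metrics`.
#' @param ... Unused.
#' @return The per-class metrics tibble.
#' @export
tidy.stage_metrics <- function(x, ...) x$per_class

#' Plot per-fold metrics of a cross-validation fit
#'
#' @param object A `stage_cv`.
#' @param ... Unused.
#' @return A ggplot: per-fold macro metrics, one line per metric.
#' @export
autoplot.stage_cv <- function(object, ...) {
  df <- object$per_fold |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(title = paste("Per-fold metrics,", object$model),
                  x = "fold", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param object A `roc_curves` from [roc_one_vs_rest()].
#' @param ... Unused.
#' @return A ggplot of the per-class ROC curves with AUC in the legend.
#' @export
autoplot.roc_curves <- function(object, ...) {
  lab <- object$auc |>
    dplyr::mutate(lab = sprintf("%s (AUC %.3f)", .data$class, .data$auc))
  df <- dplyr::left_join(object$points, lab, by = "class")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$lab)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL, title = "One-vs-rest ROC") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot, actual on rows, predicted on columns.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  df$actual <- factor(df$actual, levels = rev(rownames(object)))
  df$predicted <- factor(df$predicted, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}
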
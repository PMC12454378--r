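#' Stratified fold assignment
#'
#' Partitions samples into `n_folds` folds, stratified by class: within each
#' class, a seeded random order is dealt round-robin, so per-class fold
#' counts differ by at most 1.  Every sample lands in exactly one fold.
#'
#' @param labels Class labels (factor or character).
#' @param n_folds Number of folds (5).
#' @param seed Integer seed.
#' @return Integer vector of fold indices 1..`n_folds`, with attributes
#'   `seed` and `stratified`.
#' @export
make_folds <- function(labels, n_folds = 5L, seed = 42L) {
  labels <- as.factor(labels)
  counts <- table(droplevels(labels))
  if (any(counts < n_folds)) {
    stop("every class needs at least ", n_folds, " members; smallest has ",
         min(counts))
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      ix <- which(labels == cl)
      ix <- ix[sample(length(ix))]
      fold[ix] <- rep_len(seq_len(n_folds), length(ix))
    }
  })
  structure(fold, seed = as.integer(seed), stratified = TRUE,
            n_folds = as.integer(n_folds))
}

#' Confusion matrix
#'
#' Counts of actual class (rows) vs predicted class (columns), in the fixed
#' class order CN, MCI, AD (or the supplied `classes`).
#'
#' @param y_true,y_pred Equal-length label vectors drawn from `classes`.
#' @param classes Class order (default [stage_classes()]).
#' @return A `confusion_matrix` (classed integer matrix).
#' @export
confusion <- function(y_true, y_pred, classes = stage_classes()) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(y_true, levels = classes),
             factor(y_pred, levels = classes))
  structure(matrix(as.integer(m), length(classes), length(classes),
                   dimnames = list(actual = classes, predicted = classes)),
            class = c("confusion_matrix", "matrix", "array"))
}

# Safe ratio: zero denominator reports 0 and raises the flag.
ratio0 <- function(num, den, flag_env) {
  if (den == 0) {
    flag_env$flagged <- TRUE
    return(0)
  }
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' For each class c a one-vs-rest reduction gives TP, FP, TN, FN, from which
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), specificity = TN/(TN+FP) and
#' F1 = 2TP/(2TP+FP+FN) are computed; macro averages are their unweighted
#' means.  Overall multiclass accuracy is trace/total.  A zero denominator
#' reports the metric as 0 and sets the per-class `flagged` column.
#'
#' @param cm A [confusion()] matrix.
#' @return A `stage_metrics` object: list with `per_class` (tibble), `macro`
#'   (named numeric) and `accuracy` (overall).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") ||
              (is.matrix(cm) && nrow(cm) == ncol(cm)))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  rows <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    fl <- new.env()
    fl$flagged <- FALSE
    tibble::tibble(
      class = classes[i], tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy = ratio0(tp + tn, tp + tn + fp + fn, fl),
      precision = ratio0(tp, tp + fp, fl),
      recall = ratio0(tp, tp + fn, fl),
      specificity = ratio0(tn, tn + fp, fl),
      f1 = ratio0(2 * tp, 2 * tp + fp + fn, fl),
      flagged = fl$flagged)
  })
  per_class <- dplyr::bind_rows(rows)
  macro <- colMeans(per_class[, c("accuracy", "precision", "recall",
                                  "specificity", "f1")])
  structure(list(per_class = per_class, macro = macro,
                 accuracy = sum(diag(cm)) / total),
            class = "stage_metrics")
}

#' @export
print.stage_metrics <- function(x, ...) {
  cat(sprintf("overall accuracy %.4f | macro: P %.4f R %.4f F1 %.4f Sp %.4f\n",
              x$accuracy, x$macro["precision"], x$macro["recall"],
              x$macro["f1"], x$macro["specificity"]))
  print(x$per_class)
  invisible(x)
}

#' One-vs-rest ROC curves
#'
#' For each class, sweeps a threshold over that class's score column and
#' records (false-positive rate, true-positive rate) pairs; the area under
#' the curve is the trapezoidal integral.  A class absent from `y_true`
#' yields an NA AUC and is flagged.
#'
#' @param y_true Label vector.
#' @param scores Numeric matrix, one column per class (named, or in
#'   `classes` order).
#' @param classes Class order.
#' @return A `roc_curves` object: list with `points` (tibble: class, fpr,
#'   tpr, threshold), `auc` (tibble: class, auc, flagged) and `macro_auc`.
#' @export
roc_one_vs_rest <- function(y_true, scores, classes = stage_classes()) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- classes
  y_true <- as.character(y_true)
  pts <- list(); aucs <- list()
  for (cl in classes) {
    truth <- as.integer(y_true == cl)
    s <- scores[, cl]
    n_pos <- sum(truth); n_neg <- sum(1 - truth)
    if (n_pos == 0 || n_neg == 0) {
      aucs[[cl]] <- tibble::tibble(class = cl, auc = NA_real_, flagged = TRUE)
      next
    }
    ord <- order(s, decreasing = TRUE)
    tp <- cumsum(truth[ord]); fp <- cumsum(1 - truth[ord])
    # collapse tied thresholds to the last index of each tie group
    keep <- c(diff(s[ord]) != 0, TRUE)
    tpr <- c(0, tp[keep] / n_pos)
    fpr <- c(0, fp[keep] / n_neg)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
    pts[[cl]] <- tibble::tibble(class = cl, fpr = fpr, tpr = tpr,
                                threshold = c(Inf, s[ord][keep]))
    aucs[[cl]] <- tibble::tibble(class = cl, auc = auc, flagged = FALSE)
  }
  auc_tbl <- dplyr::bind_rows(aucs)
  structure(list(points = dplyr::bind_rows(pts), auc = auc_tbl,
                 macro_auc = mean(auc_tbl$auc, na.rm = TRUE)),
            class = "roc_curves")
}

train_head <- function(model, data, cfg, seed) {
  switch(model,
         svm = train_svm(data, cfg %||% svm_config()),
         knn = train_knn(data, cfg %||% knn_config(1L)),
         dnn = {
           c2 <- cfg %||% dnn_config(input_width =
                                       ncol(feature_matrix(data)))
           c2$seed <- as.integer(seed)
           train_dnn(data, c2)
         },
         stop("unknown model: ", model))
}

#' Cross-validate a classifier head
#'
#' The 5-fold protocol: per fold, train on the other four folds (the DNN
#' additionally holds out its stratified 80:20 inner validation split for
#' early stopping) and predict the held-out fold, so every sample is tested
#' exactly once.  Reports per-fold confusion matrices and metrics, their
#' unweighted fold mean, pooled (count-weighted) metrics over the summed
#' confusion matrix, and one-vs-rest ROC curves from the stacked scores.
#'
#' @param data Feature-set tibble from [compute_feature_set()].
#' @param model `"svm"`, `"knn"` or `"dnn"`.
#' @param cfg Optional head config ([svm_config()], [knn_config()],
#'   [dnn_config()]).
#' @param folds Fold assignment from [make_folds()] (default: 5 folds at
#'   `seed`).
#' @param seed Seed for fold assignment and DNN training.
#' @param augment_fn Optional function taking the training-fold feature
#'   tibble and returning extra (augmented) feature rows to append for
#'   training only.  Augmented ids must derive from training ids (an
#'   `_augN` suffix); the harness asserts they are disjoint from the test
#'   fold.
#' @return A `stage_cv` object.
#' @export
cross_validate <- function(data, model = c("svm", "knn", "dnn"), cfg = NULL,
                           folds = NULL, seed = 42L, augment_fn = NULL) {
  model <- match.arg(model)
  y <- factor(as.character(data$label), levels = stage_classes())
  classes <- levels(droplevels(y))
  if (is.null(folds)) folds <- make_folds(y, 5L, seed = seed)
  stopifnot(length(folds) == nrow(data))
  n_folds <- attr(folds, "n_folds") %||% max(folds)
  # partition property asserted every run
  stopifnot(sort(unique(folds)) == seq_len(n_folds),
            length(folds) == nrow(data))
  preds <- vector("list", n_folds)
  cms <- vector("list", n_folds)
  fold_metrics <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_ix <- which(folds == f)
    train_ix <- which(folds != f)
    train_data <- data[train_ix, ]
    if (!is.null(augment_fn)) {
      extra <- augment_fn(train_data)
      if (!is.null(extra) && nrow(extra) > 0) {
        base_ids <- sub("_aug[0-9]+$", "", extra$id)
        test_ids <- data$id[test_ix]
        if (any(extra$id %in% test_ids) || any(base_ids %in% test_ids)) {
          stop("augmented samples leak into test fold ", f)
        }
        if (!all(base_ids %in% train_data$id)) {
          stop("augmented samples must derive from training-fold images")
        }
        train_data <- dplyr::bind_rows(train_data, extra)
      }
    }
    fit <- tryCatch(
      train_head(model, train_data, cfg, seed = derive_seed(seed, paste0("fold", f))),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    test_data <- data[test_ix, ]
    lab <- predict(fit, test_data, type = "class")
    sc <- predict(fit, test_data, type = "score")
    cms[[f]] <- confusion(y[test_ix], lab, classes = classes)
    fold_metrics[[f]] <- metrics_from_confusion(cms[[f]])
    preds[[f]] <- tibble::tibble(id = data$id[test_ix], fold = f,
                                 label = as.character(y[test_ix]),
                                 pred = as.character(lab)) |>
      dplyr::bind_cols(tibble::as_tibble(sc, .name_repair = ~ paste0("score_", .x)))
  }
  predictions <- dplyr::bind_rows(preds)
  pooled_cm <- Reduce(`+`, lapply(cms, unclass))
  pooled_cm <- structure(pooled_cm, class = c("confusion_matrix", "matrix",
                                              "array"))
  per_fold <- dplyr::bind_rows(lapply(seq_len(n_folds), function(f) {
    m <- fold_metrics[[f]]
    tibble::tibble(fold = f, accuracy = m$accuracy,
                   macro_precision = m$macro[["precision"]],
                   macro_recall = m$macro[["recall"]],
                   macro_f1 = m$macro[["f1"]],
                   macro_specificity = m$macro[["specificity"]])
  }))
  score_cols <- grep("^score_", names(predictions), value = TRUE)
  roc <- roc_one_vs_rest(predictions$label,
                         as.matrix(predictions[, score_cols]) |>
                           `colnames<-`(sub("^score_", "", score_cols)),
                         classes = classes)
  structure(list(model = model, n = nrow(data), n_folds = n_folds,
                 folds = folds, per_fold = per_fold,
                 fold_metrics = fold_metrics, confusion = cms,
                 pooled_confusion = pooled_cm,
                 metrics_pooled = metrics_from_confusion(pooled_cm),
                 accuracy_mean = mean(per_fold$accuracy),
                 accuracy_pooled = sum(diag(pooled_cm)) / sum(pooled_cm),
                 predictions = predictions, roc = roc, seed = seed),
            class = "stage_cv")
}

#' @export
print.stage_cv <- function(x, ...) {
  cat(sprintf("<stage_cv %s | n = %d, %d folds | accuracy %.4f (fold mean), %.4f (pooled) | macro AUC %.4f>\n",
              x$model, x$n, x$n_folds, x$accuracy_mean, x$accuracy_pooled,
              x$roc$macro_auc))
  invisible(x)
}
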
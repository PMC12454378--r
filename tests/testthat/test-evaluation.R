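test_that("fold assignment partitions samples with balanced strata", {
  y <- rep(stage_classes(), each = 25)
  f <- make_folds(y, 5, seed = 1)
  expect_length(f, 75)
  expect_equal(sort(unique(f)), 1:5)
  # per-fold per-class counts all equal 5
  for (cl in stage_classes()) {
    expect_true(all(table(f[y == cl]) == 5))
  }
  # 10 samples in 5 folds -> every fold size 2
  f2 <- make_folds(rep(c("CN", "MCI"), 5), 5, seed = 2)
  expect_true(all(table(f2) == 2))
  expect_identical(make_folds(y, 5, seed = 7), make_folds(y, 5, seed = 7))
  expect_error(make_folds(c("CN", "CN", "MCI"), 5), "at least")
})

test_that("uneven classes still differ by at most one per fold", {
  withr::with_seed(3, y <- sample(rep(stage_classes(), c(23, 17, 11))))
  f <- make_folds(y, 5, seed = 3)
  for (cl in stage_classes()) {
    counts <- table(factor(f[y == cl], levels = 1:5))
    expect_lte(max(counts) - min(counts), 1)
  }
})

test_that("confusion matrices count actual x predicted pairs", {
  cm <- confusion(c("CN", "CN", "AD"), c("CN", "MCI", "AD"))
  expect_equal(cm["CN", "CN"], 1L)
  expect_equal(cm["CN", "MCI"], 1L)
  expect_equal(cm["AD", "AD"], 1L)
  expect_equal(sum(cm), 3L)
  y <- sample(stage_classes(), 100, replace = TRUE)
  p <- sample(stage_classes(), 100, replace = TRUE)
  expect_equal(sum(confusion(y, p)), 100L)
  perfect <- confusion(y, y)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusion("CN", "XX"), "unknown")
})

test_that("metrics reproduce hand arithmetic on a 2-class matrix", {
  cm <- structure(matrix(c(50L, 5L, 10L, 35L), 2, 2,
                         dimnames = list(actual = c("a", "b"),
                                         predicted = c("a", "b"))),
                  class = c("confusion_matrix", "matrix", "array"))
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 0.85)
  a <- m$per_class[m$per_class$class == "a", ]
  expect_equal(a$recall, 50 / 60)
  expect_equal(a$precision, 50 / 55)
  expect_equal(a$specificity, 35 / 40)
  expect_equal(a$f1, 100 / (100 + 5 + 10))
})

test_that("a diagonal confusion matrix yields perfect metrics", {
  cm <- confusion(rep(stage_classes(), 4), rep(stage_classes(), 4))
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$f1 == 1))
  expect_true(all(m$macro == 1))
})

test_that("metrics match the label-level oracle on random 3-class data", {
  withr::with_seed(40, {
    for (i in 1:1000) {
      n <- sample(5:40, 1)
      y <- sample(stage_classes(), n, replace = TRUE)
      p <- sample(stage_classes(), n, replace = TRUE)
      m <- metrics_from_confusion(confusion(y, p))
      orc <- oracle_metrics(y, p, stage_classes())
      for (cl in stage_classes()) {
        row <- m$per_class[m$per_class$class == cl, ]
        expect_equal(unname(unlist(row[, names(orc[[cl]])])), unname(orc[[cl]]),
                     tolerance = 1e-12)
      }
      expect_equal(m$accuracy, mean(y == p), tolerance = 1e-12)
      # F1 is the harmonic mean of its own precision and recall
      ok <- m$per_class$precision + m$per_class$recall > 0
      expect_equal(m$per_class$f1[ok],
                   2 * m$per_class$precision[ok] * m$per_class$recall[ok] /
                     (m$per_class$precision[ok] + m$per_class$recall[ok]),
                   tolerance = 1e-12)
    }
  })
})

test_that("zero denominators report 0 with a flag instead of NaN", {
  cm <- confusion(rep("CN", 5), rep("CN", 5))
  m <- metrics_from_confusion(cm)
  mci <- m$per_class[m$per_class$class == "MCI", ]
  expect_equal(mci$precision, 0)
  expect_equal(mci$recall, 0)
  expect_true(mci$flagged)
  expect_false(any(is.nan(unlist(m$per_class[, 6:10]))))
})

test_that("ROC analysis recovers perfect, null, and reversed scores", {
  y <- rep(stage_classes(), each = 10)
  onehot <- sapply(stage_classes(), function(cl) as.numeric(y == cl))
  roc <- roc_one_vs_rest(y, onehot)
  expect_equal(roc$auc$auc, rep(1, 3))
  expect_equal(roc$macro_auc, 1)
  # monotone curves
  expect_true(all(unlist(tapply(roc$points$tpr, roc$points$class,
                                function(v) diff(v) >= 0))))
  withr::with_seed(41, {
    y2 <- sample(stage_classes(), 600, replace = TRUE)
    s2 <- matrix(rnorm(1800), 600, 3, dimnames = list(NULL, stage_classes()))
    null_roc <- roc_one_vs_rest(y2, s2)
    expect_true(all(abs(null_roc$auc$auc - 0.5) < 0.1))
    rev_roc <- roc_one_vs_rest(y2, -s2)
    expect_equal(rev_roc$auc$auc, 1 - null_roc$auc$auc, tolerance = 1e-9)
  })
  # absent class flagged
  one <- roc_one_vs_rest(rep("CN", 5), matrix(rnorm(15), 5, 3,
                                              dimnames = list(NULL, stage_classes())))
  expect_true(one$auc$flagged[one$auc$class == "MCI"])
})

test_that("trapezoidal AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(42, {
    y <- sample(c("CN", "MCI"), 80, replace = TRUE)
    s <- rnorm(80) + 0.8 * (y == "CN")
    scores <- cbind(CN = s, MCI = -s, AD = rnorm(80))
  })
  roc <- roc_one_vs_rest(y, scores, classes = c("CN", "MCI"))
  ref <- as.numeric(pROC::auc(pROC::roc(response = as.integer(y == "CN"),
                                        predictor = s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc$auc$auc[roc$auc$class == "CN"], ref, tolerance = 1e-9)
})

test_that("cross-validation tests every sample exactly once and matches pooled accuracy", {
  blobs <- make_blobs(15, sd = 0.3, seed = 43)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  cv <- cross_validate(fs, "knn", folds = make_folds(fs$label, 5, 1), seed = 1)
  expect_equal(sort(cv$predictions$id), sort(fs$id))
  expect_equal(sum(sapply(cv$confusion, sum)), nrow(fs))
  expect_equal(cv$accuracy_pooled,
               sum(diag(cv$pooled_confusion)) / nrow(fs), tolerance = 1e-12)
  expect_equal(cv$accuracy_pooled, mean(cv$predictions$label == cv$predictions$pred))
  # count-weighted fold mean equals pooled accuracy when folds are equal size
  expect_equal(mean(cv$per_fold$accuracy), cv$accuracy_pooled, tolerance = 1e-12)
})

test_that("an oracle-like separable task scores 1.0 in every fold and chance data near 1/3", {
  blobs <- make_blobs(15, sd = 0.05, seed = 44)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  cv <- cross_validate(fs, "svm", seed = 2)
  expect_true(all(cv$per_fold$accuracy == 1))
  withr::with_seed(45, {
    Xr <- matrix(rnorm(150 * 4), 150, 4)
    yr <- rep(stage_classes(), each = 50)
  })
  fsr <- make_feature_tibble(Xr, yr)
  cvr <- cross_validate(fsr, "knn", seed = 3)
  expect_lt(abs(cvr$accuracy_mean - 1 / 3), 0.15)
})

test_that("tidy and glance summarize a cross-validation fit", {
  blobs <- make_blobs(10, sd = 0.2, seed = 46)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  cv <- cross_validate(fs, "knn", seed = 4)
  td <- tidy(cv)
  expect_equal(nrow(td), 5 * 3 * 5)  # folds x classes x metrics
  expect_setequal(unique(td$metric),
                  c("accuracy", "precision", "recall", "specificity", "f1"))
  g <- glance(cv)
  expect_equal(nrow(g), 1)
  expect_equal(g$model, "knn")
  expect_true(g$accuracy_mean >= 0 && g$accuracy_mean <= 1)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(cv$roc), "ggplot")
  expect_s3_class(autoplot(cv$pooled_confusion), "ggplot")
  expect_equal(sum(tidy(cv$pooled_confusion)$n), 30)
})

test_that("augmented training rows may not leak into test folds", {
  blobs <- make_blobs(10, sd = 0.2, seed = 47)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  # a well-behaved augmenter: jitter training rows, suffix ids
  good <- function(train_data) {
    extra <- train_data[1:5, ]
    extra$id <- paste0(extra$id, "_aug1")
    extra
  }
  cv <- cross_validate(fs, "knn", folds = make_folds(fs$label, 5, 5),
                       seed = 5, augment_fn = good)
  expect_equal(sort(cv$predictions$id), sort(fs$id))
  # a leaking augmenter: returns rows whose ids sit in the test fold
  folds <- make_folds(fs$label, 5, 6)
  bad <- function(train_data) {
    leak <- fs[which(folds == 1)[1], ]
    leak$id <- paste0(leak$id, "_aug1")
    leak
  }
  expect_error(cross_validate(fs, "knn", folds = folds, seed = 6,
                              augment_fn = bad), "leak|derive")
})
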
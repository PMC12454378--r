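test_that("linearly separable blobs are fit perfectly by a linear SVM", {
  blobs <- make_blobs(30, sd = 0.15, seed = 20)
  fs <- make_feature_tibble(blobs$X[1:60, ], blobs$y[1:60])  # CN vs MCI
  fit <- train_svm(fs, svm_config(kernel = "linear"))
  expect_equal(mean(as.character(predict(fit, fs)) == as.character(fs$label)), 1)
  scores <- predict(fit, fs, type = "score")
  expect_equal(dim(scores), c(60L, 2L))
})

test_that("the XOR layout defeats a linear kernel but not the RBF kernel", {
  X <- rbind(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE),
             matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  X <- X[rep(1:4, each = 10), ] + matrix(rnorm(80, sd = 0.05), 40, 2)
  y <- rep(c("CN", "CN", "MCI", "MCI"), each = 10)
  fs <- make_feature_tibble(X, y)
  lin <- train_svm(fs, svm_config(kernel = "linear"))
  expect_lte(mean(as.character(predict(lin, fs)) == as.character(fs$label)), 0.75)
  rbf <- train_svm(fs, svm_config(kernel = "radial", gamma = 1))
  expect_equal(mean(as.character(predict(rbf, fs)) == as.character(fs$label)), 1)
})

test_that("the one-vs-rest SVM returns one score per class on 3-class data", {
  blobs <- make_blobs(20, sd = 0.2, seed = 21)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  fit <- train_svm(fs)
  sc <- predict(fit, fs, type = "score")
  expect_equal(colnames(sc), stage_classes())
  expect_equal(mean(as.character(predict(fit, fs)) == as.character(fs$label)), 1)
  one <- make_feature_tibble(blobs$X[1:20, ], blobs$y[1:20])
  expect_error(train_svm(one), "2 classes")
})

test_that("SVM standardization is fitted on training data only", {
  blobs <- make_blobs(20, sd = 0.2, seed = 22)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  fit <- train_svm(fs)
  X <- feature_matrix(fs)
  expect_equal(fit$std$center, colMeans(X))
  expect_equal(fit$std$scale, apply(X, 2, sd))
  # predictions on mutated copies of test rows do not alter the model
  q <- feature_matrix(fs)[1:5, ] * 100
  invisible(predict(fit, q))
  expect_equal(fit$std$center, colMeans(X))
})

test_that("KNN memorizes training points and degenerates gracefully at k = n", {
  blobs <- make_blobs(10, sd = 0.3, seed = 23)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  fit1 <- train_knn(fs, knn_config(1))
  expect_equal(mean(predict(fit1, fs) == fs$label), 1)  # zero training error
  fitn <- train_knn(fs[1:21, ], knn_config(21))
  # k = n: global majority (CN has 10, MCI 10, AD 1 -> tie broken by nearest)
  pred <- predict(fitn, fs[22:30, ])
  expect_true(all(as.character(pred) %in% stage_classes()))
  expect_error(train_knn(fs[1:3, ], knn_config(10)), "exceeds")
})

test_that("KNN agrees with an exhaustive-distance oracle and class::knn", {
  withr::with_seed(24, {
    Xtr <- matrix(rnorm(40), 20, 2)
    ytr <- sample(stage_classes(), 20, replace = TRUE)
    Xte <- matrix(rnorm(16), 8, 2)
  })
  fs <- make_feature_tibble(Xtr, ytr)
  for (k in c(1, 3)) {
    fit <- train_knn(fs, knn_config(k))
    pred <- as.character(predict(fit, Xte))
    # oracle on the same standardized space
    Xs <- sweep(sweep(Xtr, 2, colMeans(Xtr)), 2, apply(Xtr, 2, sd), "/")
    Qs <- sweep(sweep(Xte, 2, colMeans(Xtr)), 2, apply(Xtr, 2, sd), "/")
    for (i in 1:8) {
      d <- sqrt(rowSums((Xs - matrix(Qs[i, ], 20, 2, byrow = TRUE))^2))
      nn <- order(d)[1:k]
      tab <- table(ytr[nn])
      winners <- names(tab)[tab == max(tab)]
      want <- if (length(winners) == 1) winners else ytr[order(d)[1]]
      expect_equal(pred[i], want)
    }
    if (k == 1 && requireNamespace("class", quietly = TRUE)) {
      ref <- as.character(class::knn(Xs, Qs, factor(ytr), k = 1))
      expect_equal(pred, ref)
    }
  }
})

test_that("the MLP separates clean Gaussian blobs", {
  blobs <- make_blobs(100, sd = 0.25, seed = 0)
  withr::with_seed(0, idx <- sample(300))
  tr <- idx[1:240]; te <- idx[241:300]
  fs <- make_feature_tibble(blobs$X, blobs$y)
  cfg <- dnn_config(input_width = 2, hidden_width = 32, seed = 0)
  fit <- train_dnn(fs[tr, ], cfg)
  acc <- mean(predict(fit, fs[te, ]) == fs$label[te])
  expect_gte(acc, 0.95)
  probs <- predict(fit, fs[te, ], type = "score")
  expect_equal(unname(rowSums(probs)), rep(1, 60), tolerance = 1e-9)
})

test_that("the MLP scores chance on label-shuffled data", {
  blobs <- make_blobs(100, sd = 0.25, seed = 1)
  withr::with_seed(1, ysh <- sample(blobs$y))
  fs <- make_feature_tibble(blobs$X, ysh)
  cfg <- dnn_config(input_width = 2, hidden_width = 32, seed = 1)
  fit <- train_dnn(fs[1:225, ], cfg)
  acc <- mean(predict(fit, fs[226:300, ]) == fs$label[226:300])
  expect_gte(acc, 1 / 3 - 0.1)
  expect_lte(acc, 1 / 3 + 0.15)
})

test_that("MLP training is bit-for-bit reproducible under a fixed seed", {
  blobs <- make_blobs(20, sd = 0.3, seed = 2)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  cfg <- dnn_config(input_width = 2, hidden_width = 16, epochs = 10, seed = 11)
  f1 <- train_dnn(fs, cfg)
  f2 <- train_dnn(fs, cfg)
  expect_identical(f1$net$W, f2$net$W)
  expect_identical(predict(f1, fs, type = "score"),
                   predict(f2, fs, type = "score"))
  expect_error(train_dnn(fs, dnn_config(input_width = 5)), "width")
})

test_that("prediction contracts: empty input and width mismatches", {
  blobs <- make_blobs(10, sd = 0.2, seed = 3)
  fs <- make_feature_tibble(blobs$X, blobs$y)
  for (fit in list(train_svm(fs), train_knn(fs))) {
    expect_length(predict(fit, fs[0, ]), 0)
    expect_error(predict(fit, matrix(1, 2, 5)), "width")
  }
})

test_that("flip-only augmentation doubles the set with exact mirrors", {
  withr::with_seed(30, imgs <- lapply(1:3, function(i) matrix(runif(64), 8, 8)))
  spec <- augmentation_spec(ops = "flip", seed = 5)
  out <- augment(imgs, c("CN", "MCI", "AD"), spec, n_out = 6)
  expect_length(out$images, 6)
  expect_equal(out$labels[4:6], c("CN", "MCI", "AD"))
  for (i in 1:3) {
    expect_equal(as.matrix(out$images[[i + 3]]), imgs[[i]][, 8:1])
  }
  expect_true(all(grepl("_aug", out$ids[4:6])))
})

test_that("augmentation is reproducible under its seed and identity ops are exact", {
  withr::with_seed(31, imgs <- lapply(1:4, function(i) matrix(runif(256), 16, 16)))
  labs <- c("CN", "CN", "MCI", "AD")
  spec <- augmentation_spec(seed = 9)
  a1 <- augment(imgs, labs, spec, n_out = 10)
  a2 <- augment(imgs, labs, spec, n_out = 10)
  expect_identical(a1$images, a2$images)
  expect_identical(a1$ids, a2$ids)
  # zero-magnitude rotation is a pixel-identical copy
  spec0 <- augmentation_spec(ops = "rotate", rotate_deg = 0, seed = 1)
  a0 <- augment(imgs[1], "CN", spec0, n_out = 2)
  expect_equal(as.matrix(a0$images[[2]]), imgs[[1]], tolerance = 1e-12)
  expect_error(augment(list(), character(), spec), "empty")
})
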
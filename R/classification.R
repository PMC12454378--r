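# Classifier heads: one-vs-rest SVM (established solver), k-nearest
# neighbour with the nearest-single-neighbour tie rule, and the deep MLP.
# All heads standardize features using training-fold statistics only.

fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(center = mu, scale = sdv)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

resolve_xy <- function(data) {
  if (is.data.frame(data)) {
    X <- feature_matrix(data)
    y <- factor(as.character(data$label), levels = stage_classes())
    y <- droplevels(y)
  } else stop("expected a feature-set tibble from compute_feature_set()")
  if (anyNA(X) || anyNA(y)) stop("feature set contains missing values")
  list(X = X, y = y)
}

#' SVM configuration
#'
#' Kernel settings for the one-vs-rest support vector machine.  The radial
#' basis function kernel is the default head.  `gamma = NULL` resolves at fit
#' time to `1 / (n_features * mean feature variance)` of the standardized
#' training matrix.
#'
#' @param kernel `"radial"` (default), `"linear"`, `"polynomial"` or
#'   `"sigmoid"`.
#' @param C Soft-margin cost, > 0.
#' @param gamma RBF/polynomial/sigmoid scale, > 0, or NULL for the default.
#' @param degree Polynomial degree.
#' @param coef0 Offset for polynomial/sigmoid kernels.
#' @return An `svm_config` list.
#' @export
svm_config <- function(kernel = c("radial", "linear", "polynomial", "sigmoid"),
                       C = 1, gamma = NULL, degree = 3, coef0 = 0) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, is.null(gamma) || gamma > 0)
  structure(list(kernel = kernel, C = C, gamma = gamma, degree = degree,
                 coef0 = coef0), class = "svm_config")
}

#' Train the one-vs-rest SVM head
#'
#' Fits one binary SVM per class (that class vs the rest) on standardized
#' features; prediction takes the class with the largest binary decision
#' value.  The quadratic-programming solver is `e1071::svm` (libsvm); this
#' function owns the multiclass reduction and the standardization contract.
#'
#' @param data Feature-set tibble from [compute_feature_set()] with >= 2
#'   classes present.
#' @param cfg An [svm_config()].
#' @return A `stage_svm` model.
#' @export
train_svm <- function(data, cfg = svm_config()) {
  xy <- resolve_xy(data)
  if (nlevels(xy$y) < 2) stop("need at least 2 classes to train an SVM")
  std <- fit_standardizer(xy$X)
  Xs <- apply_standardizer(std, xy$X)
  gamma <- cfg$gamma %||% (1 / (ncol(Xs) * max(mean(apply(Xs, 2, var)), 1e-12)))
  fits <- lapply(levels(xy$y), function(cl) {
    yy <- factor(ifelse(xy$y == cl, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(Xs, yy, kernel = cfg$kernel, cost = cfg$C, gamma = gamma,
               degree = cfg$degree, coef0 = cfg$coef0, scale = FALSE,
               probability = FALSE)
  })
  names(fits) <- levels(xy$y)
  structure(list(fits = fits, std = std, classes = levels(xy$y),
                 cfg = cfg, gamma = gamma, n_features = ncol(Xs)),
            class = "stage_svm")
}

#' @export
predict.stage_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  if (nrow(X) == 0) {
    return(if (type == "class") factor(character(), levels = object$classes)
           else matrix(numeric(), 0, length(object$classes),
                       dimnames = list(NULL, object$classes)))
  }
  if (ncol(X) != object$n_features) {
    stop("feature width ", ncol(X), " does not match training width ",
         object$n_features)
  }
  Xs <- apply_standardizer(object$std, X)
  scores <- vapply(object$fits, function(f) {
    dv <- attr(predict(f, Xs, decision.values = TRUE), "decision.values")
    # orient so larger = more "pos"
    if (colnames(dv)[1] == "pos/rest") dv[, 1] else -dv[, 1]
  }, numeric(nrow(Xs)))
  scores <- matrix(scores, nrow = nrow(Xs),
                   dimnames = list(NULL, object$classes))
  if (type == "score") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' KNN configuration
#'
#' @param k Neighbour count, >= 1.  The pipeline default is 1.
#' @return A `knn_config` list (Euclidean metric).
#' @export
knn_config <- function(k = 1L) {
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), metric = "euclidean"),
            class = "knn_config")
}

#' Train the k-nearest-neighbour head
#'
#' Stores the standardized training set; prediction assigns the majority
#' label among the k Euclidean-nearest training points, with ties broken by
#' the label of the single nearest neighbour.
#'
#' @param data Feature-set tibble; must have at least `k` rows.
#' @param cfg A [knn_config()].
#' @return A `stage_knn` model.
#' @export
train_knn <- function(data, cfg = knn_config(1L)) {
  xy <- resolve_xy(data)
  if (nrow(xy$X) < cfg$k) stop("k = ", cfg$k, " exceeds n = ", nrow(xy$X))
  std <- fit_standardizer(xy$X)
  structure(list(X = apply_standardizer(std, xy$X), y = xy$y, std = std,
                 classes = levels(xy$y), k = cfg$k, n_features = ncol(xy$X)),
            class = "stage_knn")
}

#' @export
predict.stage_knn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  if (nrow(X) == 0) {
    return(if (type == "class") factor(character(), levels = object$classes)
           else matrix(numeric(), 0, length(object$classes),
                       dimnames = list(NULL, object$classes)))
  }
  if (ncol(X) != object$n_features) {
    stop("feature width ", ncol(X), " does not match training width ",
         object$n_features)
  }
  Xs <- apply_standardizer(object$std, X)
  # squared Euclidean distances, all queries vs all training points
  d2 <- outer(rowSums(Xs^2), rowSums(object$X^2), "+") -
    2 * Xs %*% t(object$X)
  k <- object$k
  classes <- object$classes
  labs <- character(nrow(Xs))
  votes <- matrix(0, nrow(Xs), length(classes),
                  dimnames = list(NULL, classes))
  for (i in seq_len(nrow(Xs))) {
    ord <- order(d2[i, ])
    nn <- ord[seq_len(k)]
    tab <- table(factor(object$y[nn], levels = classes))
    votes[i, ] <- as.numeric(tab) / k
    winners <- names(tab)[tab == max(tab)]
    labs[i] <- if (length(winners) == 1) winners else
      as.character(object$y[nn[1]])  # tie: nearest single neighbour
  }
  if (type == "score") return(votes)
  factor(labs, levels = classes)
}

#' DNN configuration
#'
#' Hyperparameters of the deep multilayer-perceptron head: 256 inputs, 9
#' hidden ReLU layers, 3-way softmax output, Adam at learning rate 0.01,
#' batch size 32, at most 50 epochs with dropout 0.3 between hidden layers,
#' L2 weight decay 0.001, and early stopping when the inner-validation loss
#' fails to improve for 10 consecutive epochs.  Hidden width defaults to a
#' constant 128 units per layer.
#'
#' @param input_width Feature width (256).
#' @param hidden_layers Number of hidden layers (9).
#' @param hidden_width Units per hidden layer (128), scalar or per-layer.
#' @param learning_rate Adam step size (0.01).
#' @param batch_size Mini-batch size (32).
#' @param epochs Maximum epochs (50).
#' @param dropout Dropout rate between hidden layers (0.3).
#' @param l2 L2 weight-decay coefficient (0.001).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (10).
#' @param val_frac Inner validation fraction (0.2, the 80:20 split).
#' @param output_width Number of classes (3).
#' @param seed Seed for initialization, the inner split, batch order and
#'   dropout masks.
#' @return A `dnn_config` list.
#' @export
dnn_config <- function(input_width = 256L, hidden_layers = 9L,
                       hidden_width = 128L, learning_rate = 0.01,
                       batch_size = 32L, epochs = 50L, dropout = 0.3,
                       l2 = 0.001, early_stop_patience = 10L,
                       val_frac = 0.2, output_width = 3L, seed = 1L) {
  stopifnot(input_width > 0, hidden_layers > 0, all(hidden_width > 0),
            learning_rate > 0, batch_size > 0, epochs > 0,
            dropout >= 0, dropout < 1, l2 >= 0, early_stop_patience > 0,
            val_frac > 0, val_frac < 1, output_width > 1)
  hw <- if (length(hidden_width) == 1) rep(hidden_width, hidden_layers) else
    hidden_width
  stopifnot(length(hw) == hidden_layers)
  structure(list(input_width = as.integer(input_width),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_width = as.integer(hw),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout, l2 = l2,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_frac = val_frac, output_width = as.integer(output_width),
                 seed = as.integer(seed)),
            class = "dnn_config")
}

#' Train the deep neural-network head
#'
#' Fits the multilayer perceptron described by [dnn_config()] on standardized
#' features, holding out a stratified 20% inner validation split for early
#' stopping and restoring the best-validation weights.  Training is
#' reproducible bit-for-bit under a fixed seed in single-threaded mode.
#'
#' @param data Feature-set tibble whose feature width equals
#'   `cfg$input_width`.
#' @param cfg A [dnn_config()].
#' @return A `stage_dnn` model.
#' @export
train_dnn <- function(data, cfg = dnn_config()) {
  xy <- resolve_xy(data)
  if (ncol(xy$X) != cfg$input_width) {
    stop("feature width ", ncol(xy$X), " does not match cfg$input_width ",
         cfg$input_width)
  }
  classes <- levels(xy$y)
  if (length(classes) != cfg$output_width) {
    stop("output_width ", cfg$output_width, " does not match ",
         length(classes), " classes present")
  }
  std <- fit_standardizer(xy$X)
  Xs <- apply_standardizer(std, xy$X)
  widths <- c(cfg$input_width, cfg$hidden_width, cfg$output_width)
  fit <- mlp_train(Xs, as.integer(xy$y), widths,
                   lr = cfg$learning_rate, batch_size = cfg$batch_size,
                   epochs = cfg$epochs, dropout = cfg$dropout, l2 = cfg$l2,
                   patience = cfg$early_stop_patience,
                   val_frac = cfg$val_frac, seed = cfg$seed)
  structure(list(net = fit$net, std = std, classes = classes, cfg = cfg,
                 val_loss = fit$val_loss, best_epoch = fit$best_epoch,
                 epochs_run = fit$epochs_run, n_features = ncol(Xs)),
            class = "stage_dnn")
}

#' @export
predict.stage_dnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  if (nrow(X) == 0) {
    return(if (type == "class") factor(character(), levels = object$classes)
           else matrix(numeric(), 0, length(object$classes),
                       dimnames = list(NULL, object$classes)))
  }
  if (ncol(X) != object$n_features) {
    stop("feature width ", ncol(X), " does not match training width ",
         object$n_features)
  }
  probs <- mlp_predict_prob(object$net, apply_standardizer(object$std, X))
  colnames(probs) <- object$classes
  if (type == "score") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' Augmentation specification
#'
#' Seeded random augmentation of training images.  Operations: `rotate`
#' (uniform in +/- `rotate_deg`), `flip` (horizontal mirror), `shift`
#' (translation up to +/- `shift_frac` of the side), `scale` (zoom in
#' `scale_range`), `crop` (central crop to `crop_frac`, resized back), and
#' `gaussian_noise` (additive, SD `noise_sigma`).  Deterministic under
#' `seed`; intended for training folds only.
#'
#' @param ops Character subset of the operations above.
#' @param rotate_deg,shift_frac,scale_range,crop_frac,noise_sigma Magnitudes.
#' @param seed Integer seed.
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(ops = c("rotate", "flip", "shift", "scale",
                                      "crop", "gaussian_noise"),
                              rotate_deg = 15, shift_frac = 0.1,
                              scale_range = c(0.9, 1.1), crop_frac = 0.9,
                              noise_sigma = 0.02, seed = 1L) {
  ops <- match.arg(ops, several.ok = TRUE)
  stopifnot(rotate_deg >= 0, shift_frac >= 0, length(scale_range) == 2,
            all(scale_range > 0), crop_frac > 0, crop_frac <= 1,
            noise_sigma >= 0)
  structure(list(ops = ops, rotate_deg = rotate_deg, shift_frac = shift_frac,
                 scale_range = scale_range, crop_frac = crop_frac,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "augmentation_spec")
}

apply_augmentation_op <- function(px, op, spec) {
  nr <- nrow(px); nc <- ncol(px)
  resize_back <- function(im) as_pixel_matrix(
    EBImage::imageData(EBImage::resize(EBImage::Image(im), w = nr, h = nc)))
  out <- switch(op,
    flip = px[, rev(seq_len(nc)), drop = FALSE],
    rotate = {
      ang <- runif(1, -spec$rotate_deg, spec$rotate_deg)
      if (ang == 0) px else {
        r <- EBImage::rotate(EBImage::Image(px), ang,
                             output.dim = c(nr, nc), bg.col = 0)
        as_pixel_matrix(EBImage::imageData(r))
      }
    },
    shift = {
      dv <- round(runif(2, -spec$shift_frac, spec$shift_frac) * c(nr, nc))
      as_pixel_matrix(EBImage::imageData(
        EBImage::translate(EBImage::Image(px), v = c(dv[1], dv[2]), bg.col = 0)))
    },
    scale = {
      s <- runif(1, spec$scale_range[1], spec$scale_range[2])
      z <- EBImage::resize(EBImage::Image(px), w = max(2, round(nr * s)),
                           h = max(2, round(nc * s)))
      zm <- as_pixel_matrix(EBImage::imageData(z))
      if (s >= 1) {  # centre-crop back
        r0 <- (nrow(zm) - nr) %/% 2; c0 <- (ncol(zm) - nc) %/% 2
        zm[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
      } else {       # pad back with background
        out <- matrix(0, nr, nc)
        r0 <- (nr - nrow(zm)) %/% 2; c0 <- (nc - ncol(zm)) %/% 2
        out[r0 + seq_len(nrow(zm)), c0 + seq_len(ncol(zm))] <- zm
        out
      }
    },
    crop = {
      side_r <- max(2, round(nr * spec$crop_frac))
      side_c <- max(2, round(nc * spec$crop_frac))
      r0 <- (nr - side_r) %/% 2; c0 <- (nc - side_c) %/% 2
      resize_back(px[r0 + seq_len(side_r), c0 + seq_len(side_c), drop = FALSE])
    },
    gaussian_noise = pmin(pmax(px + rnorm(length(px), sd = spec$noise_sigma),
                               0), 1),
    stop("unknown augmentation op: ", op))
  out
}

#' Augment a set of training images
#'
#' Keeps every original image and appends seeded random augmentations (one
#' sampled operation per extra image) until `n_out` images exist.  Labels and
#' provenance ids are inherited; augmented ids get an `_augN` suffix so the
#' cross-validation harness can assert they never leak into test folds.
#'
#' @param images List of images.
#' @param labels Class labels, one per image.
#' @param spec An [augmentation_spec()].
#' @param n_out Total output count, >= `length(images)`.
#' @param ids Optional provenance ids.
#' @return List with `images`, `labels`, `ids`, `source` (index of the
#'   originating image).
#' @export
augment <- function(images, labels, spec = augmentation_spec(),
                    n_out = 2L * length(images), ids = NULL) {
  if (length(images) == 0) stop("cannot augment an empty image set")
  stopifnot(length(labels) == length(images), n_out >= length(images))
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
  n_extra <- n_out - length(images)
  out_imgs <- as.list(images)
  out_lab <- as.character(labels)
  out_ids <- ids
  src <- seq_along(images)
  withr::with_seed(spec$seed, {
    for (j in seq_len(n_extra)) {
      i <- ((j - 1) %% length(images)) + 1L
      op <- if (length(spec$ops) == 1) spec$ops else sample(spec$ops, 1)
      px <- apply_augmentation_op(as_pixel_matrix(images[[i]]), op, spec)
      out_imgs[[length(out_imgs) + 1L]] <- rewrap_like(px, images[[i]])
      out_lab <- c(out_lab, as.character(labels[i]))
      out_ids <- c(out_ids, paste0(ids[i], "_aug", j))
      src <- c(src, i)
    }
  })
  list(images = out_imgs, labels = out_lab, ids = out_ids, source = src)
}
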
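# Shared test helpers: feature-tibble builders and independent oracles.

# Wrap a plain feature matrix + labels as the tibble the classifier heads
# consume (compute_feature_set() shape).
make_feature_tibble <- function(X, labels, ids = NULL) {
  X <- as.matrix(X)
  colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_len(nrow(X)))
  dplyr::bind_cols(
    tibble::tibble(id = ids,
                   label = factor(as.character(labels),
                                  levels = stage_classes()),
                   n_patches = 0L),
    tibble::as_tibble(X))
}

# Three Gaussian blobs in d dimensions, one per stage class.
make_blobs <- function(n_per_class = 50, d = 2, sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, 3, 0, 0, 3), 3, 2, byrow = TRUE)
    if (d > 2) centers <- cbind(centers, matrix(0, 3, d - 2))
    X <- NULL; y <- character()
    for (i in 1:3) {
      X <- rbind(X, matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d) +
                   matrix(centers[i, ], n_per_class, d, byrow = TRUE))
      y <- c(y, rep(stage_classes()[i], n_per_class))
    }
    list(X = X, y = y)
  })
}

# Nested-loop oracle for the local structure tensor with a rectangular
# window and replicate (clamped-index) borders.
oracle_structure_tensor <- function(gx, gy, window_size) {
  m <- (window_size - 1) %/% 2
  nr <- nrow(gx); nc <- ncol(gx)
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  out <- list(xx = matrix(0, nr, nc), xy = matrix(0, nr, nc),
              yy = matrix(0, nr, nc))
  for (r in 1:nr) for (c in 1:nc) {
    for (dr in -m:m) for (dc in -m:m) {
      rr <- clamp(r + dr, nr); cc <- clamp(c + dc, nc)
      out$xx[r, c] <- out$xx[r, c] + gx[rr, cc]^2
      out$xy[r, c] <- out$xy[r, c] + gx[rr, cc] * gy[rr, cc]
      out$yy[r, c] <- out$yy[r, c] + gy[rr, cc]^2
    }
  }
  out
}

# Per-pixel oracle for soft orientation binning: for each pixel, find the
# two bin centres bracketing theta and split the vote by angular distance.
oracle_cell_histogram <- function(mu, theta, n_bins = 8, period = 2 * pi) {
  w <- period / n_bins
  centers <- (seq_len(n_bins) - 0.5) * w
  bins <- numeric(n_bins)
  for (i in seq_along(mu)) {
    th <- theta[i] %% period
    # circular distances to every centre
    d <- abs(th - centers)
    d <- pmin(d, period - d)
    lo <- which.min(d)
    if (d[lo] < 1e-15) {
      bins[lo] <- bins[lo] + mu[i]
      next
    }
    # the second bin is the neighbour on the side of theta
    ang_lo <- centers[lo]
    diffc <- (th - ang_lo) %% period
    hi <- if (diffc < period / 2) lo %% n_bins + 1 else
      (lo - 2) %% n_bins + 1
    d_hi <- abs(th - centers[hi]); d_hi <- min(d_hi, period - d_hi)
    bins[lo] <- bins[lo] + mu[i] * (1 - d[lo] / w)
    bins[hi] <- bins[hi] + mu[i] * (1 - d_hi / w)
  }
  bins
}

# Literal double-loop evaluation of the orientation-shift binarization.
oracle_binarize <- function(v1, v2) {
  bits <- matrix(0L, 8, 8)
  for (k in 0:7) for (e in 0:7) {
    bits[k + 1, e + 1] <- as.integer(v1[k + 1] >= v2[((k + e) %% 8) + 1])
  }
  bits
}

# Per-class metric oracle computed directly from label vectors.
oracle_metrics <- function(y_true, y_pred, classes) {
  res <- list()
  for (cl in classes) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- sum(y_true != cl & y_pred != cl)
    sdiv <- function(a, b) if (b == 0) 0 else a / b
    res[[cl]] <- c(accuracy = sdiv(tp + tn, tp + tn + fp + fn),
                   precision = sdiv(tp, tp + fp),
                   recall = sdiv(tp, tp + fn),
                   specificity = sdiv(tn, tn + fp),
                   f1 = sdiv(2 * tp, 2 * tp + fp + fn))
  }
  res
}

rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Random dyadic-valued image: sums/differences with dyadic constants are
# exact in binary floating point, so shift-invariance can be asserted exactly.
dyadic_image <- function(nr, nc, seed = 1) {
  withr::with_seed(seed, matrix(round(runif(nr * nc) * 64) / 64, nr, nc))
}

tmp_nifti <- function(arr, spacing = c(1, 1, 1), gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".nii.gz" else ".nii")
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- spacing
  RNifti::writeNifti(nim, path)
  path
}
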
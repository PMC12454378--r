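#' Gradient magnitude and orientation of a patch
#'
#' Converts the central-difference gradients of a patch to polar form:
#' magnitude \eqn{\mu = \sqrt{g_x^2 + g_y^2}} and the quadrant-aware angle of
#' \eqn{(g_x, g_y)} mapped to \[0, 2pi).  With `signed = FALSE` orientations
#' are folded to \[0, pi) (unsigned gradients).
#'
#' @param patch Numeric matrix (any size >= 3 x 3; 16 x 16 in the pipeline).
#' @param signed Use the full circle (default) or fold to half.
#' @return A `polar_field`: list with matrices `magnitude` and `angle`.
#' @export
polar_gradients <- function(patch, signed = TRUE) {
  g <- image_gradients(patch)
  mu <- sqrt(g$gx^2 + g$gy^2)
  th <- atan2(g$gy, g$gx) %% (2 * pi)
  if (!signed) th <- th %% pi
  structure(list(magnitude = mu, angle = th, signed = signed),
            class = "polar_field")
}

# Soft (bilinear) orientation binning of a set of pixels.
# Bin b covers angles [b*w, (b+1)*w), w = period/n_bins, with its centre at
# (b + 0.5)*w; each magnitude vote is split linearly between the two bins
# whose centres bracket theta, wrapping circularly.  Total vote mass is
# conserved: sum(bins) == sum(mu).
soft_bin_votes <- function(mu, theta, n_bins = 8L, period = 2 * pi) {
  p <- theta / (period / n_bins) - 0.5
  f <- floor(p)
  frac <- p - f
  lo <- (as.integer(f) %% n_bins + n_bins) %% n_bins
  hi <- (lo + 1L) %% n_bins
  bins <- numeric(n_bins)
  for (b in 0:(n_bins - 1L)) {
    bins[b + 1L] <- sum(mu[lo == b] * (1 - frac[lo == b])) +
      sum(mu[hi == b] * frac[hi == b])
  }
  bins
}

#' 8-bin orientation histogram of one cell
#'
#' Accumulates each pixel's gradient magnitude into 8 orientation bins of 45
#' degrees, splitting every vote linearly between the two nearest bin centres
#' (soft binning with circular wrap) to avoid aliasing at bin boundaries.
#' Vote mass is conserved: the bins sum to the cell's total magnitude.
#'
#' @param field A `polar_field` from [polar_gradients()].
#' @param rows,cols Integer index ranges of the cell within the field
#'   (typically 4 x 4 pixels).
#' @param n_bins Number of orientation bins (8).
#' @return Numeric vector of `n_bins` non-negative vote accumulators.
#' @export
cell_histogram <- function(field, rows, cols, n_bins = 8L) {
  stopifnot(inherits(field, "polar_field"))
  stopifnot(all(rows >= 1), all(rows <= nrow(field$magnitude)),
            all(cols >= 1), all(cols <= ncol(field$magnitude)))
  period <- if (field$signed) 2 * pi else pi
  soft_bin_votes(as.vector(field$magnitude[rows, cols]),
                 as.vector(field$angle[rows, cols]),
                 n_bins = n_bins, period = period)
}

#' Per-cell histograms of a 16 x 16 patch
#'
#' Splits the patch into a 4 x 4 grid of 4 x 4-pixel cells (row-major) and
#' computes the 8-bin orientation histogram of each.
#'
#' @param patch 16 x 16 numeric matrix.
#' @inheritParams polar_gradients
#' @return 16 x 8 matrix: one row per cell (row-major scan), one column per
#'   orientation bin.
#' @export
patch_cell_histograms <- function(patch, signed = TRUE) {
  stopifnot(nrow(patch) == 16, ncol(patch) == 16)
  field <- polar_gradients(patch, signed = signed)
  out <- matrix(0, 16, 8)
  cell <- 1L
  for (ci in 1:4) {
    for (cj in 1:4) {
      out[cell, ] <- cell_histogram(field,
                                    rows = (4 * (ci - 1) + 1):(4 * ci),
                                    cols = (4 * (cj - 1) + 1):(4 * cj))
      cell <- cell + 1L
    }
  }
  out
}

#' Assemble the 128-dimensional patch descriptor
#'
#' Concatenates the 16 cell histograms (cells scanned row-major, bins
#' innermost) into a 128-value vector, then applies block normalization:
#' the 4 x 4 cell grid is tiled into four non-overlapping 2 x 2-cell blocks,
#' each block's 32 values are L2-normalized (with an epsilon guard), clipped
#' at `clip`, and renormalized.  Set `normalize = FALSE` for raw votes or
#' `clip = NULL` to skip clipping.
#'
#' @param patch 16 x 16 numeric matrix.
#' @param normalize Apply block normalization (default TRUE).
#' @param clip Clipping ceiling after the first normalization (0.2), or NULL.
#' @param eps Normalization guard.
#' @inheritParams polar_gradients
#' @return Numeric vector of length 128 with attribute `cells` (the 16 x 8
#'   histogram matrix before normalization).
#' @export
assemble_descriptor <- function(patch, normalize = TRUE, clip = 0.2,
                                eps = 1e-6, signed = TRUE) {
  cells <- patch_cell_histograms(patch, signed = signed)
  vec <- as.vector(t(cells))  # cell-major, bins innermost
  if (normalize) {
    # block b collects cells {(i,j), (i,j+1), (i+1,j), (i+1,j+1)} for
    # i,j in {1,3}: blocks tile the cell grid without overlap
    for (bi in c(1L, 3L)) {
      for (bj in c(1L, 3L)) {
        cell_ids <- as.integer(c((bi - 1) * 4 + bj, (bi - 1) * 4 + bj + 1,
                                 bi * 4 + bj, bi * 4 + bj + 1))
        idx <- as.vector(vapply(cell_ids, function(ci) (ci - 1L) * 8L + 1:8,
                                integer(8)))
        v <- vec[idx]
        v <- v / sqrt(sum(v^2) + eps^2)
        if (!is.null(clip)) {
          v <- pmin(v, clip)
          v <- v / sqrt(sum(v^2) + eps^2)
        }
        vec[idx] <- v
      }
    }
  }
  structure(vec, cells = cells)
}

#' Cyclically shift an orientation histogram
#'
#' Rotates the 8 bins by `eps` positions: `out[k] = in[(k + eps) mod 8]`
#' (0-based bin indices).
#'
#' @param hist Numeric vector of 8 bins.
#' @param eps Integer shift in 0..7.
#' @return Shifted 8-bin vector.
#' @export
shift_histogram <- function(hist, eps) {
  stopifnot(length(hist) == 8)
  if (length(eps) != 1 || eps %% 1 != 0 || eps < 0 || eps > 7) {
    stop("shift must be an integer in 0..7, got ", eps)
  }
  hist[((0:7 + eps) %% 8) + 1]
}

#' Binarized orientation-shift comparison of two cells
#'
#' For every bin k (0..7) and shift eps (0..7) sets
#' `bit(k, eps) = 1` iff `v1(k) >= v2((k + eps) mod 8)`; ties yield 1.
#' The bit matrix encodes how one cell's orientation profile dominates its
#' neighbour's under all cyclic shifts.
#'
#' @param c1,c2 Numeric 8-bin histograms.
#' @return 8 x 8 binary (0/1 integer) matrix; rows index k, columns index eps.
#' @export
binarize_pair <- function(c1, c2) {
  stopifnot(length(c1) == 8, length(c2) == 8)
  bits <- matrix(0L, 8, 8, dimnames = list(k = 0:7, eps = 0:7))
  for (e in 0:7) {
    bits[, e + 1L] <- as.integer(c1 >= shift_histogram(c2, e))
  }
  bits
}

#' Default cell pairing: 4-neighbourhood of the 4 x 4 cell grid
#'
#' Right- and down-neighbour pairs over the row-major 4 x 4 cell grid:
#' 12 horizontal + 12 vertical = 24 pairs.
#'
#' @return Two-column integer matrix of (cell_a, cell_b) indices in 1..16.
#' @export
default_cell_pairs <- function() {
  pairs <- NULL
  for (i in 1:4) {
    for (j in 1:4) {
      id <- (i - 1) * 4 + j
      if (j < 4) pairs <- rbind(pairs, c(id, id + 1L))
      if (i < 4) pairs <- rbind(pairs, c(id, id + 4L))
    }
  }
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("cell_a", "cell_b")
  pairs
}

#' Orientation-shift binary code of a patch
#'
#' Applies [binarize_pair()] to every listed pair of cell histograms
#' (default: the 24 grid-adjacent pairs), yielding 24 x 64 bits.
#'
#' @param cells 16 x 8 matrix of cell histograms
#'   (from [patch_cell_histograms()]).
#' @param pairs Two-column matrix of cell index pairs (1..16).
#' @return A `shift_code`: list with `pairs` and `bits` (list of 8 x 8
#'   binary matrices, one per pair).
#' @export
patch_shift_code <- function(cells, pairs = default_cell_pairs()) {
  stopifnot(is.matrix(cells), nrow(cells) == 16, ncol(cells) == 8)
  pairs <- as.matrix(pairs)
  if (any(pairs < 1 | pairs > 16)) stop("cell pair index out of 1..16")
  bits <- lapply(seq_len(nrow(pairs)), function(i) {
    binarize_pair(cells[pairs[i, 1], ], cells[pairs[i, 2], ])
  })
  structure(list(pairs = pairs, bits = bits), class = "shift_code")
}

# Per-pair bit counts: a compact 24-value summary of a shift code, appended
# to the descriptor when the shift-code channel is enabled.
shift_code_counts <- function(code) {
  vapply(code$bits, sum, numeric(1))
}

#' Pool patch descriptors into one image feature vector
#'
#' Bridges a variable number of patch descriptors to a fixed-length
#' classifier input.  Default pooling concatenates the element-wise mean and
#' element-wise max over patches: 128 + 128 = 256 values.  `"mean"` keeps the
#' mean only (128 values).  Pooling is permutation-invariant in the patches.
#'
#' @param descs List of 128-value descriptors, or a matrix with one row per
#'   patch.  An empty input yields a zero vector with a warning.
#' @param method `"mean_max"` (default) or `"mean"`.
#' @return Numeric feature vector (length 256 or 128) with attribute
#'   `n_patches`.
#' @export
aggregate_image_features <- function(descs, method = c("mean_max", "mean")) {
  method <- match.arg(method)
  if (is.list(descs)) {
    lens <- lengths(descs)
    if (length(descs) > 0 && length(unique(lens)) > 1) {
      stop("inconsistent descriptor lengths: ",
           paste(unique(lens), collapse = ", "))
    }
    m <- if (length(descs)) do.call(rbind, lapply(descs, as.numeric)) else
      matrix(numeric(), 0, 128)
  } else {
    m <- as.matrix(descs)
  }
  d <- if (ncol(m) > 0) ncol(m) else 128L
  if (nrow(m) == 0) {
    warning("no patch descriptors: returning zero feature vector")
    out <- numeric(if (method == "mean_max") 2 * d else d)
    return(structure(out, n_patches = 0L))
  }
  mean_part <- colMeans(m)
  out <- switch(method,
                mean_max = c(mean_part, apply(m, 2, max)),
                mean = mean_part)
  structure(out, n_patches = nrow(m))
}

#' Per-slice feature extraction
#'
#' The descriptor pipeline for one image: Harris detection, 16 x 16 patch
#' extraction, 128-dim descriptor per patch, pooled into a fixed-length
#' feature vector.  Optionally appends the 24 per-pair bit counts of the
#' orientation-shift code (averaged over patches).
#'
#' @param img Numeric matrix or `slice_image` (preprocessed).
#' @param cfg [harris_config()].
#' @param pool Pooling method for [aggregate_image_features()].
#' @param shift_code Append shift-code bit-count features (default FALSE).
#' @param normalize,clip Passed to [assemble_descriptor()].
#' @return Numeric feature vector (256 by default; +24 with `shift_code`),
#'   with attribute `n_patches`.
#' @export
slice_features <- function(img, cfg = harris_config(),
                           pool = c("mean_max", "mean"),
                           shift_code = FALSE, normalize = TRUE, clip = 0.2) {
  pool <- match.arg(pool)
  pts <- suppressWarnings(harris_points(img, cfg))
  if (nrow(pts) == 0) {
    warning("no interest points detected; zero feature vector")
    d <- if (pool == "mean_max") 256L else 128L
    return(structure(numeric(d + if (shift_code) 24L else 0L), n_patches = 0L))
  }
  patches <- extract_patches(img, pts)
  descs <- lapply(patches, assemble_descriptor,
                  normalize = normalize, clip = clip)
  out <- aggregate_image_features(descs, method = pool)
  if (shift_code) {
    counts <- vapply(descs, function(d) {
      shift_code_counts(patch_shift_code(attr(d, "cells")))
    }, numeric(24))
    out2 <- c(as.numeric(out), rowMeans(counts) / 64)  # scale to [0,1]
    out <- structure(out2, n_patches = attr(out, "n_patches"))
  }
  out
}

#' Feature extraction over a set of labelled images
#'
#' Runs [slice_features()] on every image and assembles the tidy feature set
#' consumed by the classifier heads: one row per image with `id`, `label`,
#' `n_patches` and feature columns `f001..f256`.
#'
#' @param images List of images (matrices / `slice_image`s).
#' @param labels Factor or character vector of class labels, one per image.
#' @param ids Optional character ids (defaults to `img_001` ...).
#' @param ... Passed to [slice_features()].
#' @return A tibble; feature columns are prefixed `f`.
#' @export
compute_feature_set <- function(images, labels, ids = NULL, ...) {
  stopifnot(length(images) == length(labels))
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
  feats <- lapply(images, slice_features, ...)
  m <- do.call(rbind, lapply(feats, as.numeric))
  colnames(m) <- sprintf("f%03d", seq_len(ncol(m)))
  out <- tibble::tibble(id = ids,
                        label = factor(as.character(labels),
                                       levels = stage_classes()),
                        n_patches = vapply(feats, function(f)
                          as.integer(attr(f, "n_patches")), integer(1)))
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

#' Feature matrix of a feature set
#'
#' @param fs Tibble from [compute_feature_set()].
#' @return Numeric matrix of the `f`-prefixed columns, rownames = ids.
#' @export
feature_matrix <- function(fs) {
  cols <- grep("^f[0-9]+$", names(fs), value = TRUE)
  m <- as.matrix(fs[, cols])
  rownames(m) <- fs$id
  m
}
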
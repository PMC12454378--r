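#' Central-difference image gradients
#'
#' Horizontal and vertical gradients of an intensity image by (unscaled)
#' central differences,
#' \eqn{g_x(r,c) = I(r, c+1) - I(r, c-1)} and
#' \eqn{g_y(r,c) = I(r-1, c) - I(r+1, c)}
#' (rows increase downward, so \eqn{g_y} points "up" the image).  Borders use
#' replicate padding, giving one-sided differences there.
#'
#' @param img Numeric matrix or `slice_image`, at least 3 x 3.
#' @return A `gradient_field`: list with matrices `gx` and `gy`.
#' @export
image_gradients <- function(img) {
  px <- as_pixel_matrix(img)
  if (nrow(px) < 3 || ncol(px) < 3) {
    stop("image too small for gradients (need >= 3 x 3, got ",
         nrow(px), " x ", ncol(px), ")")
  }
  p <- pad_replicate(px, 1L)
  nr <- nrow(px); nc <- ncol(px)
  rows <- 1L + seq_len(nr); cols <- 1L + seq_len(nc)
  gx <- p[rows, cols + 1L, drop = FALSE] - p[rows, cols - 1L, drop = FALSE]
  gy <- p[rows - 1L, cols, drop = FALSE] - p[rows + 1L, cols, drop = FALSE]
  structure(list(gx = gx, gy = gy), class = "gradient_field")
}

#' Harris detector configuration
#'
#' @param k Harris response constant, in (0, 0.25).  The classic choice 0.04
#'   is the default.
#' @param window_size Odd side length of the local summation window.
#' @param window_type `"rectangular"` (uniform weights, the default) or
#'   `"gaussian"`.
#' @param rel_threshold Keep maxima with response at least this fraction of
#'   the global maximum response; in (0, 1].
#' @param nms_radius Non-maximum suppression radius in pixels.
#' @param max_points Cap on points per slice, by descending response.
#' @param border Margin (pixels) inside which points are discarded so a
#'   16 x 16 patch fits; 8 by default.
#' @return A `harris_config` list.
#' @export
harris_config <- function(k = 0.04, window_size = 5L,
                          window_type = c("rectangular", "gaussian"),
                          rel_threshold = 0.01, nms_radius = 5L,
                          max_points = 200L, border = 8L) {
  window_type <- match.arg(window_type)
  stopifnot(k > 0, k < 0.25, window_size %% 2 == 1,
            rel_threshold > 0, rel_threshold <= 1,
            nms_radius >= 0, max_points >= 1, border >= 0)
  structure(list(k = k, window_size = as.integer(window_size),
                 window_type = window_type, rel_threshold = rel_threshold,
                 nms_radius = as.integer(nms_radius),
                 max_points = as.integer(max_points),
                 border = as.integer(border)),
            class = "harris_config")
}

#' Local structure tensor of a gradient field
#'
#' Per-pixel windowed sums of the gradient products
#' \eqn{[\sum g_x^2, \sum g_x g_y; \sum g_x g_y, \sum g_y^2]} under the
#' configured window function (rectangular or Gaussian).  The result is
#' symmetric positive semi-definite at every pixel.
#'
#' @param grad A `gradient_field` from [image_gradients()].
#' @param cfg A [harris_config()].
#' @return A `structure_tensor`: list of matrices `xx`, `xy`, `yy`.
#' @export
structure_tensor <- function(grad, cfg = harris_config()) {
  stopifnot(inherits(grad, "gradient_field"))
  w <- if (cfg$window_type == "rectangular") {
    matrix(1, cfg$window_size, cfg$window_size)
  } else {
    gaussian_kernel(cfg$window_size, cfg$window_size / 5)$weights
  }
  structure(list(xx = conv2_replicate(grad$gx * grad$gx, w),
                 xy = conv2_replicate(grad$gx * grad$gy, w),
                 yy = conv2_replicate(grad$gy * grad$gy, w)),
            class = "structure_tensor")
}

#' Harris corner response
#'
#' \eqn{R = \det(M) - k\,\mathrm{trace}(M)^2} per pixel, where M is the local
#' structure tensor.  Both eigenvalues large (a corner) gives R > 0; one
#' dominant eigenvalue (an edge) gives R <= 0.
#'
#' @param tensor A `structure_tensor`.
#' @param k Response constant (default 0.04).
#' @return Numeric matrix of responses.
#' @export
harris_response <- function(tensor, k = 0.04) {
  stopifnot(inherits(tensor, "structure_tensor"))
  det_m <- tensor$xx * tensor$yy - tensor$xy^2
  tr_m <- tensor$xx + tensor$yy
  det_m - k * tr_m^2
}

#' Detect interest points on a Harris response map
#'
#' Keeps pixels whose response reaches `rel_threshold` times the global
#' maximum and is a strict 3 x 3 local maximum, suppresses weaker points
#' within `nms_radius` (Euclidean), discards points within `border` pixels of
#' any edge (so a 16 x 16 patch fits), and caps the result at `max_points`
#' by descending response.
#'
#' @param response Numeric response matrix from [harris_response()].
#' @param cfg A [harris_config()].
#' @return A tibble with columns `row`, `col`, `response`, ordered by
#'   descending response.  May be empty (with a warning).
#' @export
detect_interest_points <- function(response, cfg = harris_config()) {
  stopifnot(is.matrix(response), all(is.finite(response)))
  nr <- nrow(response); nc <- ncol(response)
  mx <- max(response)
  empty <- tibble::tibble(row = integer(), col = integer(),
                          response = numeric())
  if (mx <= 0) {
    warning("no positive Harris response; no interest points")
    return(empty)
  }
  thr <- cfg$rel_threshold * mx
  # 3x3 local maxima via dilation-style shifted max
  p <- pad_replicate(response, 1L)
  neigh_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    neigh_max <- pmax(neigh_max,
                      p[1L + dr + seq_len(nr), 1L + dc + seq_len(nc), drop = FALSE])
  }
  cand <- which(response >= thr & response > neigh_max, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    warning("no interest points above threshold")
    return(empty)
  }
  b <- cfg$border
  inb <- cand[, 1] > b & cand[, 1] <= nr - b & cand[, 2] > b & cand[, 2] <= nc - b
  cand <- cand[inb, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("all candidate points fell inside the border margin")
    return(empty)
  }
  resp <- response[cand]
  ord <- order(-resp, cand[, 1], cand[, 2])  # ties broken by position
  cand <- cand[ord, , drop = FALSE]
  resp <- resp[ord]
  keep <- logical(nrow(cand))
  r2 <- as.numeric(cfg$nms_radius)^2
  for (i in seq_len(nrow(cand))) {
    if (any(keep)) {
      kept <- which(keep)
      d2 <- (cand[kept, 1] - cand[i, 1])^2 + (cand[kept, 2] - cand[i, 2])^2
      if (any(d2 <= r2)) next
    }
    keep[i] <- TRUE
    if (sum(keep) >= cfg$max_points) break
  }
  tibble::tibble(row = as.integer(cand[keep, 1]),
                 col = as.integer(cand[keep, 2]),
                 response = resp[keep])
}

#' Full Harris detection on a slice
#'
#' Convenience chain: [image_gradients()] then [structure_tensor()],
#' [harris_response()] and [detect_interest_points()].
#'
#' @inheritParams image_gradients
#' @param cfg A [harris_config()].
#' @return Tibble of interest points (see [detect_interest_points()]).
#' @export
harris_points <- function(img, cfg = harris_config()) {
  grad <- image_gradients(img)
  detect_interest_points(harris_response(structure_tensor(grad, cfg), cfg$k),
                         cfg)
}

#' Cut 16 x 16 patches around interest points
#'
#' Each patch spans rows `row - 8 .. row + 7` and columns `col - 8 .. col + 7`
#' of the source image; points must be at least 8 pixels from every border
#' (enforced upstream by [detect_interest_points()]).
#'
#' @param img Numeric matrix or `slice_image`.
#' @param points Tibble/data frame with `row`, `col` (1-based).
#' @param patch_size Side length; 16 unless you know better.
#' @return List of `patch_size` x `patch_size` matrices, in input order, each
#'   with a `center` attribute `(row, col)`.
#' @export
extract_patches <- function(img, points, patch_size = 16L) {
  px <- as_pixel_matrix(img)
  half <- patch_size %/% 2L
  lapply(seq_len(nrow(points)), function(i) {
    r <- points$row[i]; cc <- points$col[i]
    if (r - half < 1 || r + half - 1 > nrow(px) ||
        cc - half < 1 || cc + half - 1 > ncol(px)) {
      stop("interest point (", r, ", ", cc, ") too close to the border for a ",
           patch_size, " x ", patch_size, " patch")
    }
    structure(px[(r - half):(r + half - 1L), (cc - half):(cc + half - 1L)],
              center = c(row = r, col = cc))
  })
}
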
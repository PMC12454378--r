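#' Construct a slice image
#'
#' A slice image is a plain numeric matrix of intensities carrying pixel
#' spacing (mm) and provenance as attributes.  After [normalize_intensity()]
#' values lie in \[0, 1\].
#'
#' @param pixels Numeric matrix of intensities.
#' @param spacing Length-2 numeric, physical size of a pixel in mm
#'   (row direction, column direction).
#' @param source Optional source path.
#' @param index Optional slice index within the source volume.
#' @return A `slice_image` object (a classed matrix).
#' @export
slice_image <- function(pixels, spacing = c(1, 1), source = NA_character_,
                        index = NA_integer_) {
  pixels <- as_pixel_matrix(pixels)
  if (!all(is.finite(pixels))) stop("slice contains non-finite values")
  stopifnot(length(spacing) == 2, all(spacing > 0))
  structure(pixels, class = c("slice_image", "matrix", "array"),
            spacing = as.numeric(spacing), source = source,
            index = as.integer(index))
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image %d x %d, spacing %.3g x %.3g mm, range [%.3g, %.3g]>\n",
              nrow(x), ncol(x), attr(x, "spacing")[1], attr(x, "spacing")[2],
              min(x), max(x)))
  invisible(x)
}

#' Read a NIfTI brain volume
#'
#' Reads a T1-weighted MR volume in NIfTI format (`.nii` or `.nii.gz`) and
#' returns the voxel grid together with its per-axis spacing from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume_image`: list with `voxels` (3D array), `spacing`
#'   (length-3 numeric, mm) and `source`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  vox <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("cannot read '", path,
                                           "' as NIfTI: ", conditionMessage(e)))
  dims <- dim(vox)
  if (is.null(dims) || length(dims) != 3) {
    stop("'", path, "' is not a 3D volume (dims: ",
         paste(dims, collapse = "x"), ")")
  }
  spacing <- RNifti::pixdim(vox)[seq_len(3)]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- rep(1, 3)
  structure(list(voxels = array(as.numeric(vox), dims),
                 spacing = as.numeric(spacing), source = path),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image %s, spacing %s mm>\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Resample a volume to a uniform target spacing
#'
#' Trilinear resampling onto a grid with the requested per-axis voxel size.
#' The physical extent of the volume is preserved to within one voxel.
#'
#' @param vol A `volume_image` from [read_volume()].
#' @param target_spacing Numeric of length 1 or 3: desired voxel size in mm.
#' @return A `volume_image` with `spacing == target_spacing`.
#' @export
resample_volume <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "volume_image"))
  if (length(target_spacing) == 1) target_spacing <- rep(target_spacing, 3)
  if (any(target_spacing <= 0)) stop("target spacing must be strictly positive")
  dims <- dim(vol$voxels)
  extent <- dims * vol$spacing
  new_dims <- pmax(1L, as.integer(round(extent / target_spacing)))
  if (all(new_dims == dims) && all(vol$spacing == target_spacing)) return(vol)
  # voxel centres: axis coordinate of output voxel i is (i-1)*target spacing,
  # expressed in input voxel index units, clamped to the grid
  coords <- lapply(1:3, function(a) {
    x <- (seq_len(new_dims[a]) - 1) * target_spacing[a] / vol$spacing[a] + 1
    pmin(pmax(x, 1), dims[a])
  })
  out <- trilinear_sample(vol$voxels, coords[[1]], coords[[2]], coords[[3]])
  structure(list(voxels = out, spacing = as.numeric(target_spacing),
                 source = vol$source),
            class = "volume_image")
}

# Trilinear interpolation of `arr` on the tensor grid xs x ys x zs
# (1-based fractional indices, already clamped).
trilinear_sample <- function(arr, xs, ys, zs) {
  d <- dim(arr)
  f <- function(v, n) pmin(pmax(floor(v), 1), max(n - 1, 1))
  x0 <- f(xs, d[1]); y0 <- f(ys, d[2]); z0 <- f(zs, d[3])
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  tx <- xs - x0; ty <- ys - y0; tz <- zs - z0
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  out <- array(0, c(nx, ny, nz))
  TX <- array(tx, c(nx, ny, nz))
  TY <- array(rep(ty, each = nx), c(nx, ny, nz))
  TZ <- array(rep(tz, each = nx * ny), c(nx, ny, nz))
  g <- function(ix, iy, iz) arr[cbind(as.vector(array(ix, c(nx, ny, nz))),
                                      as.vector(array(rep(iy, each = nx), c(nx, ny, nz))),
                                      as.vector(array(rep(iz, each = nx * ny), c(nx, ny, nz))))]
  c000 <- g(x0, y0, z0); c100 <- g(x1, y0, z0)
  c010 <- g(x0, y1, z0); c110 <- g(x1, y1, z0)
  c001 <- g(x0, y0, z1); c101 <- g(x1, y0, z1)
  c011 <- g(x0, y1, z1); c111 <- g(x1, y1, z1)
  v <- (1 - TX) * (1 - TY) * (1 - TZ) * c000 + TX * (1 - TY) * (1 - TZ) * c100 +
    (1 - TX) * TY * (1 - TZ) * c010 + TX * TY * (1 - TZ) * c110 +
    (1 - TX) * (1 - TY) * TZ * c001 + TX * (1 - TY) * TZ * c101 +
    (1 - TX) * TY * TZ * c011 + TX * TY * TZ * c111
  array(v, c(nx, ny, nz))
}

#' Min-max intensity normalization (histogram stretching)
#'
#' Linearly stretches intensities so the slice minimum maps to 0 and the
#' maximum to 1.  The map is monotone, so pixel ordering is preserved.  With
#' `method = "percentile"` the stretch anchors are the given quantiles and the
#' result is clipped to \[0, 1\], which is robust to isolated hot pixels.
#'
#' @param img Numeric matrix or `slice_image`.
#' @param method `"minmax"` (default) or `"percentile"`.
#' @param probs Lower/upper quantiles for `method = "percentile"`.
#' @return A `slice_image` with values in \[0, 1\].  A constant input returns
#'   all zeros with a warning (degenerate stretch).
#' @export
normalize_intensity <- function(img, method = c("minmax", "percentile"),
                                probs = c(0.01, 0.99)) {
  method <- match.arg(method)
  px <- as_pixel_matrix(img)
  spacing <- attr(img, "spacing") %||% c(1, 1)
  if (method == "minmax") {
    lo <- min(px); hi <- max(px)
  } else {
    q <- quantile(px, probs = probs, names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  if (hi <= lo) {
    warning("constant image: degenerate stretch, returning all zeros")
    out <- matrix(0, nrow(px), ncol(px))
  } else {
    out <- (px - lo) / (hi - lo)
    out <- pmin(pmax(out, 0), 1)
  }
  slice_image(out, spacing = spacing,
              source = attr(img, "source") %||% NA_character_,
              index = attr(img, "index") %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrete 2D Gaussian kernel
#'
#' Evaluates the isotropic 2D Gaussian
#' \deqn{G(x, y) = \frac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/(2\sigma^2)}}
#' on the centred integer lattice of side `size`, then renormalizes the
#' weights to sum to 1.  The unnormalized evaluation is kept in
#' `$unnormalized` (its centre value at sigma = 1 is \eqn{1/(2\pi)}).
#'
#' @param size Odd integer kernel side, >= 3.  Default 5.
#' @param sigma Standard deviation in pixels, > 0.  Default 1.
#' @return A `gaussian_kernel`: list with `size`, `sigma`, `weights`
#'   (sums to 1) and `unnormalized`.
#' @export
gaussian_kernel <- function(size = 5L, sigma = 1) {
  if (size %% 2 == 0 || size < 3) stop("kernel size must be an odd integer >= 3")
  if (sigma <= 0) stop("sigma must be positive")
  m <- (size - 1) / 2
  x <- matrix(rep(-m:m, size), size, size)
  y <- t(x)
  raw <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  structure(list(size = as.integer(size), sigma = sigma,
                 weights = raw / sum(raw), unnormalized = raw),
            class = "gaussian_kernel")
}

#' Gaussian smoothing of a slice
#'
#' Convolves the slice with a normalized Gaussian kernel under replicate
#' border padding; the output has the same shape as the input.
#'
#' @param img Numeric matrix or `slice_image`.
#' @param kernel A [gaussian_kernel()] (default 5 x 5, sigma 1).
#' @return A smoothed image of the same class and shape as the input.
#' @export
smooth_slice <- function(img, kernel = gaussian_kernel(5L, 1)) {
  stopifnot(inherits(kernel, "gaussian_kernel"))
  px <- as_pixel_matrix(img)
  out <- conv2_replicate(px, kernel$weights)
  rewrap_like(out, img)
}

rewrap_like <- function(px, template) {
  if (inherits(template, "slice_image")) {
    slice_image(px, spacing = attr(template, "spacing"),
                source = attr(template, "source"),
                index = attr(template, "index"))
  } else px
}

#' Morphological cleanup of small objects
#'
#' Builds a binary support mask by Otsu thresholding, opens it with a 3 x 3
#' structuring element, removes connected components smaller than
#' `min_object_px`, and zeroes the image outside the surviving mask.
#' Foreground intensities inside surviving objects are untouched.
#'
#' @param img Numeric matrix or `slice_image` with values in \[0, 1\].
#' @param min_object_px Minimum connected-component size (pixels) to keep.
#' @return Cleaned image, same class and shape.
#' @export
morphological_cleanup <- function(img, min_object_px = 64L) {
  stopifnot(min_object_px >= 1)
  px <- as_pixel_matrix(img)
  if (min(px) >= max(px)) return(rewrap_like(px, img))  # flat: nothing to do
  th <- EBImage::otsu(EBImage::Image(px), range = range(px))
  mask <- px > th
  if (!any(mask)) {
    warning("morphological cleanup produced an empty mask")
    return(rewrap_like(px * 0, img))
  }
  opened <- EBImage::opening(EBImage::Image(mask * 1),
                             EBImage::makeBrush(3L, shape = "box"))
  lab <- EBImage::bwlabel(opened)
  labm <- as_pixel_matrix(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= min_object_px)
  final <- matrix(labm %in% keep, nrow(px), ncol(px))
  if (!any(final)) warning("no objects of at least ", min_object_px,
                           " px survived cleanup")
  rewrap_like(px * final, img)
}

#' Extract normalized 2D slices from a volume
#'
#' Selects slices along one axis — either an explicit index set or a centred
#' window of `n` slices — and returns each as a [normalize_intensity()]-ed
#' `slice_image` in ascending index order.
#'
#' @param vol A `volume_image`.
#' @param policy List with `axis` (1, 2 or 3; default 3) and either
#'   `indices` (explicit, 1-based) or `n` (centred window size).
#'   Default: 9 centred slices on axis 3.
#' @return List of `slice_image`s.
#' @export
extract_slices <- function(vol, policy = list(axis = 3L, n = 9L)) {
  stopifnot(inherits(vol, "volume_image"))
  axis <- policy$axis %||% 3L
  stopifnot(axis %in% 1:3)
  nax <- dim(vol$voxels)[axis]
  if (!is.null(policy$indices)) {
    idx <- sort(as.integer(policy$indices))
  } else {
    n <- as.integer(policy$n %||% 9L)
    if (n > nax) stop("centred window of ", n, " slices exceeds axis length ", nax)
    centre <- ceiling(nax / 2)
    half <- (n - 1) %/% 2
    idx <- seq(centre - half, length.out = n)
  }
  if (any(idx < 1 | idx > nax)) {
    stop("slice index out of range 1..", nax, ": ",
         paste(idx[idx < 1 | idx > nax], collapse = ", "))
  }
  sp <- vol$spacing[-axis]
  lapply(idx, function(i) {
    sl <- switch(axis,
                 vol$voxels[i, , ],
                 vol$voxels[, i, ],
                 vol$voxels[, , i])
    normalize_intensity(slice_image(sl, spacing = sp,
                                    source = vol$source, index = i))
  })
}
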
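#' Phantom specification
#'
#' Parameters of one synthetic brain-like slice: a bright outer "skull" ring,
#' a CSF gap, a mid-grey cortical ring of `cortical_thickness` pixels, a
#' brighter white-matter annulus, and dark central "ventricles" of relative
#' radius `ventricle_scale`, plus `irregularity` random dark notches on the
#' cortical ring (emulating sulcal widening) and additive Gaussian noise.
#' Under the default presets ventricle size grows and cortical thickness
#' shrinks from CN to MCI to AD.
#'
#' @param class_label `"CN"`, `"MCI"` or `"AD"`.
#' @param size Image side in pixels, >= 64.
#' @param ventricle_scale Ventricle radius as a fraction of the half-side.
#' @param cortical_thickness Cortical ring width in pixels.
#' @param irregularity Number of random dark notches on the cortical ring.
#' @param noise_sigma SD of additive Gaussian noise.
#' @param seed Integer seed controlling notches and noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(class_label, size = 96L, ventricle_scale = 0.16,
                         cortical_thickness = 10L, irregularity = 1L,
                         noise_sigma = 0.05, seed = 1L) {
  class_label <- match.arg(class_label, stage_classes())
  stopifnot(size >= 64, ventricle_scale > 0, ventricle_scale < 1,
            cortical_thickness >= 1, irregularity >= 0, noise_sigma >= 0)
  structure(list(class_label = class_label, size = as.integer(size),
                 ventricle_scale = ventricle_scale,
                 cortical_thickness = as.integer(cortical_thickness),
                 irregularity = as.integer(irregularity),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default class presets for the phantom generator
#'
#' The study conditions of the synthetic experiment: ventricle scale
#' increases monotonically CN -> MCI -> AD, cortical thickness decreases, and
#' structural irregularity (notch count) increases.
#'
#' @param size Image side in pixels.
#' @param noise_sigma Additive noise SD shared by all classes.
#' @return Named list of [phantom_spec()]s (seeds unset; filled per image by
#'   [make_dataset()]).
#' @export
phantom_presets <- function(size = 96L, noise_sigma = 0.03) {
  list(
    CN  = phantom_spec("CN",  size = size, ventricle_scale = 0.14,
                       cortical_thickness = 11L, irregularity = 0L,
                       noise_sigma = noise_sigma),
    MCI = phantom_spec("MCI", size = size, ventricle_scale = 0.23,
                       cortical_thickness = 8L, irregularity = 6L,
                       noise_sigma = noise_sigma),
    AD  = phantom_spec("AD",  size = size, ventricle_scale = 0.32,
                       cortical_thickness = 5L, irregularity = 12L,
                       noise_sigma = noise_sigma))
}

#' Generate one phantom slice
#'
#' Deterministic under `spec$seed`: the same spec always renders the same
#' image, byte for byte.  Values are clipped to \[0, 1\].
#'
#' @param spec A [phantom_spec()].
#' @return A `slice_image` of side `spec$size`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$size
  brain_r <- 0.38 * s
  skull_out <- 0.44 * s
  skull_in <- 0.40 * s
  vent_r <- spec$ventricle_scale * s / 2
  cort_in <- brain_r - spec$cortical_thickness
  if (cort_in <= vent_r + 2) {
    stop("cortical_thickness ", spec$cortical_thickness,
         " too large for size ", s, " with ventricle_scale ",
         spec$ventricle_scale)
  }
  cc <- (s + 1) / 2
  r <- sqrt(outer((seq_len(s) - cc)^2, (seq_len(s) - cc)^2, "+"))
  img <- matrix(0, s, s)
  img[r <= skull_out] <- 0.95                       # skull
  img[r <= skull_in] <- 0.10                        # CSF gap
  img[r <= brain_r] <- 0.55                         # cortical grey matter
  img[r <= cort_in] <- 0.85                         # white matter
  img[r <= vent_r] <- 0.05                          # ventricles
  withr::with_seed(spec$seed, {
    if (spec$irregularity > 0) {
      ring_r <- brain_r - spec$cortical_thickness / 2
      ang <- runif(spec$irregularity, 0, 2 * pi)
      rad <- runif(spec$irregularity, 1.5, 3.5)
      for (i in seq_len(spec$irregularity)) {
        nr0 <- cc + ring_r * sin(ang[i])
        nc0 <- cc + ring_r * cos(ang[i])
        d <- sqrt(outer((seq_len(s) - nr0)^2, (seq_len(s) - nc0)^2, "+"))
        img[d <= rad[i]] <- 0.10                    # sulcal notch
      }
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(rnorm(s * s, sd = spec$noise_sigma), s, s)
    }
  })
  slice_image(pmin(pmax(img, 0), 1),
              source = sprintf("phantom:%s:seed%d", spec$class_label,
                               spec$seed))
}

jitter_spec <- function(preset, seed) {
  # per-image structural jitter around the class preset
  withr::with_seed(seed, {
    vs <- preset$ventricle_scale + rnorm(1, sd = 0.015)
    vs <- min(max(vs, 0.05), 0.45)
    ct <- preset$cortical_thickness + sample(-1:1, 1)
    ct <- max(ct, 3L)
    ir <- max(preset$irregularity + sample(-1:1, 1), 0L)
  })
  phantom_spec(preset$class_label, size = preset$size, ventricle_scale = vs,
               cortical_thickness = ct, irregularity = ir,
               noise_sigma = preset$noise_sigma, seed = seed)
}

#' Generate a labelled phantom dataset
#'
#' `n_per_class` images per class, each rendered from a seeded per-image
#' jitter of the class preset.  Fully reproducible: two calls with the same
#' arguments return byte-identical images and manifests.
#'
#' @param n_per_class Images per class (the study-scale default is 150).
#' @param presets Named list of class presets ([phantom_presets()]).
#' @param seed Global dataset seed.
#' @return A `phantom_dataset`: list with `images`, `labels` (factor),
#'   `specs` and a `manifest` tibble (`id`, `label`, `seed`).
#' @export
make_dataset <- function(n_per_class = 150L, presets = phantom_presets(),
                         seed = 7L) {
  stopifnot(n_per_class >= 1)
  specs <- list(); labels <- character(); ids <- character()
  sub_seeds <- integer()
  k <- 0L
  for (cl in names(presets)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sseed <- derive_seed(seed, sprintf("phantom_%s_%d", cl, i))
      specs[[k]] <- jitter_spec(presets[[cl]], sseed)
      labels[k] <- presets[[cl]]$class_label
      ids[k] <- sprintf("%s_%03d", cl, i)
      sub_seeds[k] <- sseed
    }
  }
  images <- lapply(specs, make_phantom)
  structure(list(images = images,
                 labels = factor(labels, levels = stage_classes()),
                 specs = specs,
                 manifest = tibble::tibble(id = ids, label = labels,
                                           seed = sub_seeds)),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset: %d images (%s)>\n", length(x$images),
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Stack jittered phantom slices into a NIfTI volume
#'
#' Thin 3D wrapper over the 2D generator: renders `n_slices` seeded jitters
#' of one spec and stacks them along the third axis, optionally writing a
#' `.nii.gz`.  Exercises [read_volume()] and [extract_slices()].
#'
#' @param spec A [phantom_spec()].
#' @param n_slices Number of stacked slices.
#' @param path Optional output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm (length 3).
#' @return A `volume_image`; written to `path` when given.
#' @export
phantom_volume <- function(spec, n_slices = 9L, path = NULL,
                           spacing = c(1, 1, 1)) {
  slices <- lapply(seq_len(n_slices), function(i) {
    sp <- spec
    sp$seed <- derive_seed(spec$seed, paste0("slice", i))
    as_pixel_matrix(make_phantom(sp))
  })
  vox <- array(unlist(slices), c(spec$size, spec$size, n_slices))
  vol <- structure(list(voxels = vox, spacing = as.numeric(spacing),
                        source = path %||% NA_character_),
                   class = "volume_image")
  if (!is.null(path)) {
    nim <- RNifti::asNifti(vox)
    RNifti::pixdim(nim) <- spacing
    RNifti::writeNifti(nim, path)
  }
  vol
}

#' Analytic test fixtures
#'
#' Small images with known structure for unit tests:
#' `corner_fixture()` draws a bright axis-aligned rectangle whose four
#' corners are known; `gradient_fixture()` is a planar ramp whose
#' central-difference gradient is exactly `magnitude * (cos(theta),
#' sin(theta))` in the interior; `impulse_fixture()` is a single unit pixel
#' on zeros.
#'
#' @param size Image side.
#' @param top,left,height,width Rectangle geometry (1-based, inclusive).
#' @param theta Gradient direction in radians.
#' @param magnitude Gradient magnitude (in central-difference units).
#' @return A numeric matrix.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
corner_fixture <- function(size = 64L, top = NULL, left = NULL,
                           height = NULL, width = NULL) {
  top <- top %||% (size %/% 4)
  left <- left %||% (size %/% 4)
  height <- height %||% (size %/% 2)
  width <- width %||% (size %/% 2)
  if (top < 1 || left < 1 || top + height - 1 > size || left + width - 1 > size) {
    stop("rectangle does not fit in a ", size, " x ", size, " image")
  }
  img <- matrix(0, size, size)
  img[top:(top + height - 1), left:(left + width - 1)] <- 1
  structure(img, corners = rbind(c(top, left),
                                 c(top, left + width - 1),
                                 c(top + height - 1, left),
                                 c(top + height - 1, left + width - 1)))
}

#' @rdname fixtures
#' @export
gradient_fixture <- function(size = 32L, theta = 0, magnitude = 1) {
  cols <- matrix(rep(seq_len(size), each = size), size, size)
  rows <- matrix(rep(seq_len(size), size), size, size)
  # gx = I(r,c+1) - I(r,c-1) = magnitude*cos(theta);
  # gy = I(r-1,c) - I(r+1,c) = magnitude*sin(theta)
  (cols * cos(theta) - rows * sin(theta)) * magnitude / 2
}

#' @rdname fixtures
#' @export
impulse_fixture <- function(size = 11L) {
  stopifnot(size %% 2 == 1)
  img <- matrix(0, size, size)
  img[(size + 1) / 2, (size + 1) / 2] <- 1
  img
}
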
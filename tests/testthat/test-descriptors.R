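test_that("polar gradients honour magnitude and angle conventions", {
  # plane with gx = 3, gy = 4 everywhere in the interior
  img <- outer(1:16, 1:16, function(r, c) (3 * c - 4 * r) / 2)
  f <- polar_gradients(img)
  expect_equal(f$magnitude[8, 8], 5)
  f1 <- polar_gradients(gradient_fixture(16, 0, 1))
  expect_equal(f1$angle[8, 8], 0)
  f2 <- polar_gradients(gradient_fixture(16, pi / 2, 1))
  expect_equal(f2$angle[8, 8], pi / 2)
})

test_that("polar gradients round-trip to cartesian", {
  withr::with_seed(8, patch <- matrix(rnorm(256), 16, 16))
  g <- image_gradients(patch)
  f <- polar_gradients(patch)
  expect_equal(f$magnitude * cos(f$angle), g$gx, tolerance = 1e-9)
  expect_equal(f$magnitude * sin(f$angle), g$gy, tolerance = 1e-9)
  expect_true(all(f$angle >= 0 & f$angle < 2 * pi))
})

test_that("soft binning sends aligned votes to one bin and splits midway votes", {
  # all angles at the centre of bin 0 (22.5 degrees)
  f <- structure(list(magnitude = matrix(1, 4, 4),
                      angle = matrix(pi / 8, 4, 4), signed = TRUE),
                 class = "polar_field")
  h <- cell_histogram(f, 1:4, 1:4)
  expect_equal(h, c(16, rep(0, 7)))
  # midway between bin 0 and bin 1 centres (45 degrees): 50/50
  f$angle <- matrix(pi / 4, 4, 4)
  h2 <- cell_histogram(f, 1:4, 1:4)
  expect_equal(h2[1:2], c(8, 8))
  expect_true(all(h2[3:8] == 0))
})

test_that("cell histograms match the per-pixel oracle and conserve vote mass", {
  withr::with_seed(9, {
    for (i in 1:100) {
      mu <- abs(rnorm(16))
      theta <- runif(16, 0, 2 * pi)
      f <- structure(list(magnitude = matrix(mu, 4, 4),
                          angle = matrix(theta, 4, 4), signed = TRUE),
                     class = "polar_field")
      h <- cell_histogram(f, 1:4, 1:4)
      expect_equal(h, oracle_cell_histogram(mu, theta), tolerance = 1e-12)
      expect_equal(sum(h), sum(mu), tolerance = 1e-9)
    }
  })
})

test_that("assembled descriptors always have 128 entries in 16 cells of 8 bins", {
  withr::with_seed(10, {
    for (i in 1:5) {
      d <- assemble_descriptor(matrix(runif(256), 16, 16))
      expect_length(d, 128)
      expect_equal(dim(attr(d, "cells")), c(16L, 8L))
    }
  })
  expect_equal(as.numeric(assemble_descriptor(matrix(0.4, 16, 16))),
               rep(0, 128))
})

test_that("block normalization bounds each block and clipping caps entries", {
  withr::with_seed(11, patch <- matrix(runif(256), 16, 16))
  d <- assemble_descriptor(patch, clip = 0.2)
  expect_true(all(d >= 0 & d <= 1 + 1e-9))
  # every 2x2-cell block has L2 norm <= 1 + eps
  for (b in 0:3) {
    bi <- c(1, 3)[b %/% 2 + 1]; bj <- c(1, 3)[b %% 2 + 1]
    cells <- c((bi - 1) * 4 + bj, (bi - 1) * 4 + bj + 1,
               bi * 4 + bj, bi * 4 + bj + 1)
    idx <- as.vector(sapply(cells, function(ci) (ci - 1) * 8 + 1:8))
    expect_lte(sqrt(sum(d[idx]^2)), 1 + 1e-9)
  }
  raw <- assemble_descriptor(patch, normalize = FALSE)
  expect_equal(sum(raw), sum(attr(raw, "cells")), tolerance = 1e-9)
})

test_that("rotating a patch by 90 degrees remaps cells and shifts bins by two", {
  withr::with_seed(12, patch <- matrix(runif(256), 16, 16))
  d0 <- patch_cell_histograms(patch)
  d1 <- patch_cell_histograms(rot90ccw(patch))
  for (ci in 1:4) for (cj in 1:4) {
    jcell <- (ci - 1) * 4 + cj
    icell <- (cj - 1) * 4 + (5 - ci)   # source cell under the rotation
    expect_equal(d1[jcell, ], d0[icell, ][((0:7 - 2) %% 8) + 1],
                 tolerance = 1e-6)
  }
  # and the unclipped assembled descriptors match after the same remapping
  a0 <- assemble_descriptor(patch, clip = NULL)
  a1 <- assemble_descriptor(rot90ccw(patch), clip = NULL)
  expect_equal(sort(as.numeric(a0)), sort(as.numeric(a1)), tolerance = 1e-6)
})

test_that("histogram shifting is a cyclic rotation with group closure", {
  h <- 1:8
  expect_equal(shift_histogram(h, 0), h)
  expect_equal(shift_histogram(h, 2), c(3, 4, 5, 6, 7, 8, 1, 2))
  expect_error(shift_histogram(h, 8), "0..7")
  expect_equal(shift_histogram(shift_histogram(h, 7), 1), h)
})

test_that("pair binarization follows the shifted >= rule with ties giving 1", {
  h <- c(5, 3, 8, 1, 9, 2, 7, 4)
  expect_true(all(binarize_pair(h, h)[, 1] == 1))  # eps = 0: reflexive >=
  expect_true(all(binarize_pair(h + 10, h) == 1))  # strict dominance
  withr::with_seed(13, {
    for (i in 1:100) {
      v1 <- rnorm(8); v2 <- rnorm(8)
      expect_identical(unname(binarize_pair(v1, v2)), oracle_binarize(v1, v2))
    }
  })
})

test_that("the >= comparison is total across mirrored bit positions", {
  withr::with_seed(14, {
    for (i in 1:50) {
      v1 <- rnorm(8); v2 <- rnorm(8)
      b12 <- binarize_pair(v1, v2)
      b21 <- binarize_pair(v2, v1)
      for (k in 0:7) for (e in 0:7) {
        expect_gte(b12[k + 1, e + 1] +
                     b21[((k + e) %% 8) + 1, ((8 - e) %% 8) + 1], 1)
      }
    }
  })
})

test_that("the patch shift code pairs grid-adjacent cells", {
  expect_equal(nrow(default_cell_pairs()), 24)
  cells <- matrix(rep(1:8, each = 16), 16, 8)
  code <- patch_shift_code(cells)
  expect_length(code$bits, 24)
  expect_true(all(vapply(code$bits, function(b) all(b[, 1] == 1), logical(1))))
  # single-pair spec reduces to binarize_pair
  one <- patch_shift_code(cells, pairs = matrix(c(1L, 2L), 1))
  expect_identical(one$bits[[1]], binarize_pair(cells[1, ], cells[2, ]))
  expect_error(patch_shift_code(cells, pairs = matrix(c(0L, 2L), 1)),
               "out of")
})

test_that("feature pooling duplicates singletons, takes mean and max, ignores order", {
  a <- runif(128); b <- runif(128)
  f1 <- aggregate_image_features(list(a))
  expect_equal(as.numeric(f1), c(a, a))
  f2 <- aggregate_image_features(list(a, b))
  expect_equal(as.numeric(f2), c((a + b) / 2, pmax(a, b)))
  expect_equal(attr(f2, "n_patches"), 2L)
  withr::with_seed(15, {
    descs <- lapply(1:7, function(i) runif(128))
    perm <- sample(7)
    expect_equal(as.numeric(aggregate_image_features(descs)),
                 as.numeric(aggregate_image_features(descs[perm])))
  })
  expect_warning(z <- aggregate_image_features(list()), "zero")
  expect_length(z, 256)
  expect_error(aggregate_image_features(list(runif(128), runif(64))),
               "inconsistent")
})

test_that("slice feature vectors are 256 long (280 with the shift code)", {
  img <- smooth_slice(make_phantom(phantom_spec("AD", seed = 2)))
  f <- slice_features(img)
  expect_length(f, 256)
  expect_gt(attr(f, "n_patches"), 0)
  fc <- slice_features(img, shift_code = TRUE)
  expect_length(fc, 280)
  expect_true(all(fc[257:280] >= 0 & fc[257:280] <= 1))
  expect_warning(fz <- slice_features(matrix(0.5, 64, 64)), "no")
  expect_equal(as.numeric(fz), rep(0, 256))
})
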
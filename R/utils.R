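# Internal helpers shared across modules.

# Pad a matrix by replicating its border rows/columns `n` deep on every side.
pad_replicate <- function(x, n) {
  nr <- nrow(x)
  nc <- ncol(x)
  ri <- c(rep(1L, n), seq_len(nr), rep(nr, n))
  ci <- c(rep(1L, n), seq_len(nc), rep(nc, n))
  x[ri, ci, drop = FALSE]
}

# 2D correlation of `x` with a (2m+1)x(2m+1) kernel under replicate padding.
# Implemented as a sum of shifted copies: exact, and fast for small kernels.
conv2_replicate <- function(x, kernel) {
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  mr <- (kr - 1L) %/% 2L
  mc <- (kc - 1L) %/% 2L
  if (kr > nrow(x) || kc > ncol(x)) {
    stop("kernel (", kr, "x", kc, ") larger than image (",
         nrow(x), "x", ncol(x), ")")
  }
  p <- pad_replicate(x, max(mr, mc))
  off <- max(mr, mc)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * p[(off - mr + i - 1L) + seq_len(nrow(x)),
                         (off - mc + j - 1L) + seq_len(ncol(x)), drop = FALSE]
    }
  }
  out
}

as_pixel_matrix <- function(img) {
  if (is.matrix(img)) return(unclass(img))
  if (is.array(img) && length(dim(img)) == 2) return(matrix(img, dim(img)[1], dim(img)[2]))
  stop("expected a 2D numeric matrix, got ", paste(class(img), collapse = "/"))
}

#' Derive a per-stage seed from the global seed
#'
#' Deterministically maps (seed, stage name) to an integer seed below
#' 2^31 - 1, so each pipeline stage draws from its own reproducible stream
#' and can be rerun in isolation.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (single string).
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) %% 1e6 * 7919 + h * 104729) %% 2147483629 + 1)
}
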
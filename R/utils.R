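# Internal numeric helpers shared across modules.

#' Normalised 1D Gaussian kernel
#'
#' @param sigma standard deviation in pixels.
#' @param radius kernel half-width; default truncates at 4 sigma.
#' @return numeric vector of odd length summing to 1.
#' @keywords internal
#' @noRd
gaussian_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense convolution operator along one axis with mirror ("reflect") boundary.
# For axis length n and kernel half-width r the matrix is n x n; n is small
# for microscopy stacks so the dense form is fast via BLAS.
reflect_conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_along(kernel)) {
      idx <- i + j - r - 1L
      while (idx < 1L || idx > n) {
        if (idx < 1L) idx <- 2L - idx
        if (idx > n) idx <- 2L * n - idx
      }
      K[i, idx] <- K[i, idx] + kernel[j]
    }
  }
  K
}

# Separable convolution of a 3D array (z, y, x) along a single axis.
convolve_axis3d <- function(vol, kernel, axis) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  K <- reflect_conv_matrix(d[axis], kernel)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- K %*% matrix(v, nrow = dv[1L])
  aperm(array(m, dv), order(perm))
}

# Anisotropic Gaussian blur of a 3D array; sigmas = (sz, sy, sx) in voxels.
gaussian_blur3d <- function(vol, sigmas) {
  stopifnot(length(sigmas) == 3L, all(sigmas >= 0))
  for (ax in 1:3) {
    if (sigmas[ax] > 0) {
      vol <- convolve_axis3d(vol, gaussian_kernel1d(sigmas[ax]), ax)
    }
  }
  vol
}

# 2D Gaussian blur of a matrix with mirror boundary.
gaussian_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel1d(sigma)
  Kr <- reflect_conv_matrix(nrow(m), k)
  Kc <- reflect_conv_matrix(ncol(m), k)
  Kr %*% m %*% t(Kc)
}

# Otsu threshold of a numeric vector/array, delegated to EBImage on the
# values rescaled to [0, 1].
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  img <- EBImage::Image(matrix((x - rng[1]) / diff(rng), nrow = 1L))
  th <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

# Largest foreground connected component of a binary matrix (8-connectivity).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) stop("mask has no foreground pixels")
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)
    message(sprintf("mask has %d components; keeping the largest (%d px)",
                    max(lab), sizes[keep]))
    mask <- lab == keep
  } else {
    mask <- lab == 1L
  }
  storage.mode(mask) <- "logical"
  mask
}

# Fill interior holes of a binary matrix.
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  EBImage::imageData(filled) > 0
}
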
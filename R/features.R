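# Per-pixel image features for the learned detector/segmenter heads.
#
# Multi-scale Gaussian smoothing, difference-of-Gaussian band-passes and
# gradient magnitudes: enough context for a small per-pixel classifier
# to separate ringed cells from background on bilayer images.

# Banded row-normalized Gaussian convolution matrix (replicate edges).
gauss_band <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  d <- outer(idx, idx, function(i, j) j - i)
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > r] <- 0
  k / rowSums(k)
}

# Separable Gaussian blur of a matrix.
blur_gauss <- function(img, sigma) {
  if (sigma <= 0) return(img)
  ky <- gauss_band(nrow(img), sigma)
  kx <- gauss_band(ncol(img), sigma)
  ky %*% img %*% t(kx)
}

# Central-difference gradient magnitude of a (pre-blurred) matrix.
grad_mag <- function(img) {
  h <- nrow(img); w <- ncol(img)
  up <- img[c(1L, seq_len(h - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  lf <- img[, c(1L, seq_len(w - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  sqrt((dn - up)^2 / 4 + (rt - lf)^2 / 4)
}

FEATURE_NAMES <- c("raw", "g1", "g2", "g4", "g8",
                   "dog12", "dog24", "dog48", "gm1", "gm2")

# Feature stack of one channel slice: (H*W) x n_features matrix.
# `norm` is the full-scale gray value used to map intensities to [0, 1].
pixel_features <- function(img, norm) {
  x <- img / norm
  g1 <- blur_gauss(x, 1); g2 <- blur_gauss(x, 2)
  g4 <- blur_gauss(x, 4); g8 <- blur_gauss(x, 8)
  f <- cbind(as.vector(x), as.vector(g1), as.vector(g2), as.vector(g4),
             as.vector(g8), as.vector(g1 - g2), as.vector(g2 - g4),
             as.vector(g4 - g8), as.vector(grad_mag(g1)),
             as.vector(grad_mag(g2)))
  colnames(f) <- FEATURE_NAMES
  f
}
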
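# Internal numeric helpers shared across modules.

# Signed integer frequencies for an n-point DFT, in FFT storage order.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

# Trapezoidal quadrature on a (possibly non-uniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Subpixel translation of a 2D image by (dx, dy) pixels via Fourier phase ramp.
# Positive dx moves content toward larger row index.
fourier_shift2d <- function(img, dx, dy) {
  d <- dim(img)
  kx <- fft_freq(d[1]) / d[1]
  ky <- fft_freq(d[2]) / d[2]
  phase <- exp(-2i * pi * (outer(kx * dx, ky * dy, "+")))
  Re(fft(fft(img) * phase, inverse = TRUE)) / length(img)
}

# Bilinear interpolation of img at fractional (row, col) positions (1-based).
# Out-of-bounds positions evaluate to 0.
bilinear <- function(img, x, y) {
  d <- dim(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  val <- numeric(length(x))
  px <- function(i, j) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
    out <- numeric(length(i))
    out[ok] <- img[cbind(i[ok], j[ok])]
    out
  }
  val <- px(x0, y0) * (1 - fx) * (1 - fy) +
    px(x0 + 1, y0) * fx * (1 - fy) +
    px(x0, y0 + 1) * (1 - fx) * fy +
    px(x0 + 1, y0 + 1) * fx * fy
  val
}

# Trilinear interpolation of a 3D array at fractional (1-based) coordinates
# given as an n x 3 matrix. Out-of-bounds positions evaluate to 0.
trilinear <- function(vol, pts) {
  d <- dim(vol)
  p0 <- floor(pts)
  f <- pts - p0
  val <- numeric(nrow(pts))
  vx <- function(i, j, k) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- numeric(length(i))
    out[ok] <- vol[cbind(i[ok], j[ok], k[ok])]
    out
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
      (if (dj) f[, 2] else 1 - f[, 2]) *
      (if (dk) f[, 3] else 1 - f[, 3])
    val <- val + w * vx(p0[, 1] + di, p0[, 2] + dj, p0[, 3] + dk)
  }
  val
}

# Uniform random unit vectors in R^3 (normalized Gaussian triples).
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Sample weighted standard deviation with frequency weights (n - 1 denominator
# on the effective count).
weighted_sd <- function(x, w) {
  n <- sum(w)
  if (n <= 1) return(0)
  m <- sum(w * x) / n
  sqrt(sum(w * (x - m)^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
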
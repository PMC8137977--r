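# Separable 2D convolution with reflective (symmetric, edge-repeating)
# boundary handling. All filtering in the package goes through these helpers
# so boundary behavior is identical everywhere.

reflect_index <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  if (r > n) stop_validation("kernel radius exceeds image size")
  c(rev(seq_len(r)), seq_len(n), seq(n, n - r + 1L))
}

# Convolve each column with kernel k (odd length), i.e. filter along the row
# (y) dimension.
conv_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  nr <- nrow(m)
  mp <- m[reflect_index(nr, r), , drop = FALSE]
  out <- matrix(0, nr, ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * mp[i:(i + nr - 1L), , drop = FALSE]
  out
}

conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  nc <- ncol(m)
  mp <- m[, reflect_index(nc, r), drop = FALSE]
  out <- matrix(0, nrow(m), nc)
  for (i in seq_along(k))
    out <- out + k[i] * mp[, i:(i + nc - 1L), drop = FALSE]
  out
}

sep_conv <- function(m, k_row, k_col) conv_cols(conv_rows(m, k_row), k_col)

# Sampled Gaussian kernel and its first two derivatives. The 0th order kernel
# is normalized to unit sum; derivative kernels are forced to zero sum so that
# constant images give an exactly zero response.
gaussian_kernel <- function(sigma, order = 0L) {
  stopifnot(order %in% 0:2)
  if (sigma <= 0) {
    if (order == 0L) return(1)
    stop_validation("derivative kernels need sigma > 0")
  }
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    "2" = (x^2 - sigma^2) / sigma^4 * g
  )
  if (order > 0L) k <- k - sum(k) / length(k)
  k
}

# Local mean over a square window (odd side), reflective boundaries.
local_mean <- function(m, window_px) {
  k <- rep(1 / window_px, window_px)
  sep_conv(m, k, k)
}
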
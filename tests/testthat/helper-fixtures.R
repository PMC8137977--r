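# Shared fixtures (built in code) and independent brute-force oracles.

# --- raster fixtures ---------------------------------------------------------

fix_hline <- function(n_px = 101, h = 31, w = n_px + 20) {
  m <- matrix(FALSE, h, w)
  m[(h + 1) %/% 2, 11:(10 + n_px)] <- TRUE
  m
}

fix_diag <- function(n_px = 101, pad = 10) {
  side <- n_px + 2 * pad
  m <- matrix(FALSE, side, side)
  m[cbind(pad + seq_len(n_px), pad + seq_len(n_px))] <- TRUE
  m
}

fix_plus_thick <- function(arm = 25, width = 5, pad = 6) {
  side <- 2 * arm + width + 2 * pad
  ctr <- pad + arm + (width + 1) %/% 2
  half <- (width - 1) %/% 2
  m <- matrix(FALSE, side, side)
  m[(ctr - half):(ctr + half), (pad + 1):(side - pad)] <- TRUE
  m[(pad + 1):(side - pad), (ctr - half):(ctr + half)] <- TRUE
  m
}

fix_T <- function(arm = 20) {
  side <- 2 * arm + 1
  m <- matrix(FALSE, side, side)
  m[arm + 1, 1:side] <- TRUE          # horizontal bar through the center
  m[1:(arm + 1), arm + 1] <- TRUE     # vertical arm meeting it
  m
}

# 1-px 8-connected digital circle (via thinning of a dense ring trace)
fix_ring <- function(r = 20) {
  side <- 2 * r + 21
  ctr <- (side + 1) / 2
  th <- seq(0, 2 * pi, length.out = 100000)
  m <- matrix(FALSE, side, side)
  m[cbind(round(ctr + r * sin(th)), round(ctr + r * cos(th)))] <- TRUE
  skeletonize(m)$mask
}

# 1-px 8-connected semicircular arc of radius r (collapse the 4-connected
# staircase left by dense rounding)
fix_semicircle <- function(r = 40) {
  th <- seq(0, pi, length.out = 100000)
  x <- round(r * cos(th)); y <- round(r * sin(th))
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  px <- cbind(x[keep], y[keep])
  repeat {
    n <- nrow(px)
    dx1 <- px[2:(n - 1), 1] - px[1:(n - 2), 1]
    dy1 <- px[2:(n - 1), 2] - px[1:(n - 2), 2]
    dx2 <- px[3:n, 1] - px[2:(n - 1), 1]
    dy2 <- px[3:n, 2] - px[2:(n - 1), 2]
    drop <- which(abs(dx1) + abs(dy1) == 1 & abs(dx2) + abs(dy2) == 1 &
                  (dx1 != dx2 | dy1 != dy2)) + 1L
    if (!length(drop)) break
    drop <- drop[c(TRUE, diff(drop) > 1L)]
    px <- px[-drop, , drop = FALSE]
  }
  side <- 2 * r + 21
  m <- matrix(FALSE, side, side)
  m[cbind(px[, 2] + 11, px[, 1] + r + 11)] <- TRUE
  m
}

# Sierpinski gasket raster (pixel (i, j) filled iff bitwAnd(i, j) == 0)
fix_sierpinski <- function(n = 243) {
  outer(0:(n - 1), 0:(n - 1), function(i, j) bitwAnd(i, j) == 0)
}

# --- independent oracles -----------------------------------------------------

# Point-in-convex-polygon by the all-same-side test (independent of the
# package's even-odd ray cast). Vertices in order; strict interior.
oracle_in_convex <- function(px, py, vx, vy) {
  n <- length(vx)
  side <- rep(0, length(px))
  ok <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    s <- sign(cr)
    ok <- ok & (s != 0)
    side <- ifelse(side == 0, s, side)
    ok <- ok & (s == side)
  }
  ok
}

oracle_count_in_convex <- function(vx, vy, shape) {
  cnt <- 0L
  for (r in seq_len(shape[1])) for (cc in seq_len(shape[2])) {
    if (oracle_in_convex(cc - 0.5, r - 0.5, vx, vy)) cnt <- cnt + 1L
  }
  cnt
}

# Direct per-pixel local mean with symmetric (edge-repeat) reflection.
oracle_local_mean <- function(m, w) {
  r <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + m[refl(i + di, nr), refl(j + dj, nc)]
    out[i, j] <- acc / w^2
  }
  out
}

# Direct 2D convolution with a separable Gaussian, symmetric reflection.
oracle_gauss_conv <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
  k2 <- outer(k, k)
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + k2[di + r + 1L, dj + r + 1L] * m[refl(i + di, nr), refl(j + dj, nc)]
    out[i, j] <- acc
  }
  out
}

# Exact two-sided signed-rank p by explicit enumeration (expand.grid over
# sign vectors; independent of the package's polynomial expansion).
oracle_signed_rank <- function(x, y) {
  d <- (y - x)[(y - x) != 0]
  n <- length(d)
  if (n == 0L) return(1)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  lo <- mean(w_all <= w_obs + 1e-9)
  hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Exact two-sided rank-sum p by enumerating subsets.
oracle_rank_sum <- function(x, y) {
  n1 <- length(x)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  w_all <- apply(combn(length(rk), n1), 2, function(s) sum(rk[s]))
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# Clean and noisy render settings used throughout the suite.
noise_clean <- function() list(speckle_sigma = 0, background_level = 0, blur_px = 0)
noise_default <- function() list(speckle_sigma = 0.3, background_level = 0.12, blur_px = 0.8)
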
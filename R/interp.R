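# Interpolation primitives shared by resampling, straightening and
# length standardization. All grids are regular; continuous positions are
# expressed in 1-based voxel coordinates (voxel centres at integers).

# Catmull-Rom cubic convolution weights for the 4-tap stencil at
# fractional offset t in [0,1). Reproduces constants and linear ramps.
.cr_weights <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  cbind(0.5 * (-t + 2 * t2 - t3),
        0.5 * (2 - 5 * t2 + 3 * t3),
        0.5 * (t + 4 * t2 - 3 * t3),
        0.5 * (-t2 + t3))
}

# Dense interpolation matrix mapping a length-n_in axis to samples at
# x_out (1-based voxel coordinates). Stencil indices are clamped at the
# borders (edge replication), which keeps row sums at 1.
.interp_matrix <- function(n_in, x_out, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  n_out <- length(x_out)
  W <- matrix(0, n_out, n_in)
  rows <- seq_len(n_out)
  if (method == "nearest") {
    i <- pmin(pmax(round(x_out), 1), n_in)
    W[cbind(rows, i)] <- 1
    return(W)
  }
  i0 <- floor(x_out)
  w <- .cr_weights(x_out - i0)
  for (k in 1:4) {
    i <- pmin(pmax(i0 + k - 2, 1), n_in)
    idx <- cbind(rows, i)
    W[idx] <- W[idx] + w[, k]
  }
  W
}

# Apply a (n_out x n_in) interpolation matrix along one axis of a 3D array.
.apply_axis <- function(a, axis, W) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  out <- W %*% m
  out <- array(out, c(nrow(W), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

# Tricubic (separable Catmull-Rom) sampling of a 3D array at arbitrary
# points (n x 3 matrix, 1-based voxel coordinates). Points outside the
# grid return `outside`; the number of such points is attached as an
# attribute. Stencils are clamped at the borders.
.sample_tricubic <- function(a, pts, outside = 0) {
  d <- dim(a)
  n <- nrow(pts)
  out <- rep(outside, n)
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
        pts[, 2] >= 1 & pts[, 2] <= d[2] &
        pts[, 3] >= 1 & pts[, 3] <= d[3]
  p <- pts[ok, , drop = FALSE]
  if (nrow(p)) {
    i0 <- floor(p)
    wx <- .cr_weights(p[, 1] - i0[, 1])
    wy <- .cr_weights(p[, 2] - i0[, 2])
    wz <- .cr_weights(p[, 3] - i0[, 3])
    acc <- numeric(nrow(p))
    for (kx in 1:4) {
      ix <- pmin(pmax(i0[, 1] + kx - 2, 1), d[1])
      for (ky in 1:4) {
        iy <- pmin(pmax(i0[, 2] + ky - 2, 1), d[2])
        wxy <- wx[, kx] * wy[, ky]
        for (kz in 1:4) {
          iz <- pmin(pmax(i0[, 3] + kz - 2, 1), d[3])
          acc <- acc + wxy * wz[, kz] * a[ix + (iy - 1) * d[1] + (iz - 1) * d[1] * d[2]]
        }
      }
    }
    out[ok] <- acc
  }
  attr(out, "n_outside") <- sum(!ok)
  out
}

# Nearest-neighbour sampling of a 3D array at arbitrary points.
.sample_nearest <- function(a, pts, outside = 0) {
  d <- dim(a)
  n <- nrow(pts)
  out <- rep(outside, n)
  r <- round(pts)
  ok <- r[, 1] >= 1 & r[, 1] <= d[1] &
        r[, 2] >= 1 & r[, 2] <= d[2] &
        r[, 3] >= 1 & r[, 3] <= d[3]
  ri <- r[ok, , drop = FALSE]
  out[ok] <- a[ri[, 1] + (ri[, 2] - 1) * d[1] + (ri[, 3] - 1) * d[1] * d[2]]
  attr(out, "n_outside") <- sum(!ok)
  out
}

# Bilinear sampling of a matrix at continuous (row, col) positions;
# positions outside the grid return 0. Used for ray casting on masks.
.sample_bilinear <- function(m, rr, cc) {
  d <- dim(m)
  out <- numeric(length(rr))
  ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
  r <- rr[ok]; c <- cc[ok]
  r0 <- pmin(floor(r), d[1] - 1L); c0 <- pmin(floor(c), d[2] - 1L)
  tr <- r - r0; tc <- c - c0
  i00 <- r0 + (c0 - 1) * d[1]
  v <- (1 - tr) * (1 - tc) * m[i00] +
       tr * (1 - tc) * m[i00 + 1] +
       (1 - tr) * tc * m[i00 + d[1]] +
       tr * tc * m[i00 + d[1] + 1]
  out[ok] <- v
  out
}

# Normalised 1D Gaussian convolution matrix (n x n) with sigma in voxel
# units; truncated at 3 sigma and row-renormalised so constants are
# preserved at the borders.
.gauss_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  W <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    i <- seq_len(n)
    src <- pmin(pmax(i + j, 1), n)
    idx <- cbind(i, src)
    W[idx] <- W[idx] + k[j + r + 1]
  }
  W / rowSums(W)
}

# Cubic-spline interpolation of a series with gaps: interior gaps are
# filled by a natural spline through the present points, gaps beyond the
# first/last present point by nearest-value extension.
.spline_fill <- function(y) {
  idx <- seq_along(y)
  present <- which(is.finite(y))
  if (length(present) < 4)
    stop("spline fill requires at least 4 present points", call. = FALSE)
  out <- y
  lo <- min(present); hi <- max(present)
  miss <- setdiff(idx, present)
  interior <- miss[miss > lo & miss < hi]
  if (length(interior))
    out[interior] <- stats::spline(present, y[present], xout = interior,
                                   method = "fmm")$y
  out[miss[miss < lo]] <- y[lo]
  out[miss[miss > hi]] <- y[hi]
  out
}
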
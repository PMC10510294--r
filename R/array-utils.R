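# Low-level 3D array primitives shared by the descriptor, warping and
# phantom code. All boundary handling is edge replication (clamped
# indices): zero padding would inject artificial structure into the
# patch-difference maps at the volume border.

#' Shift a 3D array by an integer offset with edge replication
#'
#' Returns `b` with `b[p] = a[clamp(p + offset)]`, i.e. the array resampled
#' at positions displaced by `offset`, clamping out-of-range indices to the
#' border voxel.
#'
#' @param a 3D numeric array.
#' @param offset integer vector of length 3 (x, y, z), in voxels.
#' @return 3D array of the same dimension as `a`.
#' @keywords internal
shift3d <- function(a, offset) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(offset) == 3L)
  ix <- pmin.int(pmax.int(seq_len(d[1]) + offset[1], 1L), d[1])
  iy <- pmin.int(pmax.int(seq_len(d[2]) + offset[2], 1L), d[2])
  iz <- pmin.int(pmax.int(seq_len(d[3]) + offset[3], 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

# Sum of the (2r+1) axis shifts of `a` along one axis, with edge
# replication; equivalent to replicate-padding then a running window sum.
.axis_window_sum <- function(a, r, axis) {
  out <- a
  off <- c(0L, 0L, 0L)
  for (d in seq_len(r)) {
    off[axis] <- d
    out <- out + shift3d(a, off)
    off[axis] <- -d
    out <- out + shift3d(a, off)
  }
  out
}

#' Uniform box-mean filter over an odd cubic window
#'
#' Mean of `a` over the `w^3` window centred at each voxel, separable along
#' the three axes, with edge-replication boundary handling.
#'
#' @param a 3D numeric array.
#' @param w odd window edge length in voxels.
#' @return filtered array, same dimension.
#' @keywords internal
box_mean3d <- function(a, w) {
  if (w %% 2L != 1L || w < 1L) stop("box window must be odd and positive")
  r <- (w - 1L) %/% 2L
  if (r == 0L) return(a)
  out <- .axis_window_sum(a, r, 1L)
  out <- .axis_window_sum(out, r, 2L)
  out <- .axis_window_sum(out, r, 3L)
  out / w^3
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Truncated at 3 sigma; edge replication at the borders. `sigma = 0`
#' returns the input unchanged.
#'
#' @param a 3D numeric array.
#' @param sigma standard deviation in voxels (scalar, applied per axis).
#' @return smoothed array.
#' @keywords internal
gauss_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) {
    out <- a * k[r + 1L]
    off <- c(0L, 0L, 0L)
    for (d in seq_len(r)) {
      off[axis] <- d
      out <- out + k[r + 1L + d] * shift3d(a, off)
      off[axis] <- -d
      out <- out + k[r + 1L - d] * shift3d(a, off)
    }
    a <- out
  }
  a
}

#' Periodic (FFT) Gaussian smoothing of a 3D array
#'
#' Frequency-domain Gaussian filter with periodic wrap-around. Unlike the
#' spatial edge-replicated filter, the output statistics are stationary
#' right up to the border, which matters when smoothing noise fields
#' (edge replication inflates boundary variance). Used by the phantom
#' deformation generator, where the boundary taper removes the wrap seam.
#'
#' @inheritParams gauss_smooth3d
#' @keywords internal
fft_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  k <- lapply(d, function(n) {
    f <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1))) * (2 * pi / n)
    exp(-0.5 * sigma^2 * f^2)
  })
  K <- outer(outer(k[[1]], k[[2]]), k[[3]])
  Re(stats::fft(stats::fft(a) * K, inverse = TRUE)) / prod(d)
}

#' Trilinear sampling of a 3D array at fractional voxel positions
#'
#' Coordinates are 0-based voxel positions; samples outside the grid are
#' clamped to the border (edge replication).
#'
#' @param a 3D numeric array.
#' @param x,y,z numeric vectors of equal length, 0-based voxel coordinates.
#' @return numeric vector of sampled values.
#' @keywords internal
trilinear3d <- function(a, x, y, z) {
  d <- dim(a)
  x <- pmin(pmax(x, 0), d[1] - 1)
  y <- pmin(pmax(y, 0), d[2] - 1)
  z <- pmin(pmax(z, 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(z), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1L) x0 <- rep(0, length(x))
  if (d[2] == 1L) y0 <- rep(0, length(y))
  if (d[3] == 1L) z0 <- rep(0, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v000 <- a[idx(x0, y0, z0)]; v100 <- a[idx(x1, y0, z0)]
  v010 <- a[idx(x0, y1, z0)]; v110 <- a[idx(x1, y1, z0)]
  v001 <- a[idx(x0, y0, z1)]; v101 <- a[idx(x1, y0, z1)]
  v011 <- a[idx(x0, y1, z1)]; v111 <- a[idx(x1, y1, z1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Nearest-neighbour sampling of a 3D array at fractional voxel positions
#' @inheritParams trilinear3d
#' @keywords internal
nearest3d <- function(a, x, y, z) {
  d <- dim(a)
  i <- pmin(pmax(round(x), 0), d[1] - 1)
  j <- pmin(pmax(round(y), 0), d[2] - 1)
  k <- pmin(pmax(round(z), 0), d[3] - 1)
  a[1 + i + d[1] * (j + d[2] * k)]
}

# Central-difference gradient of a 3D array along one axis (voxel units),
# one-sided at the two border slices.
grad3d <- function(a, axis) {
  d <- dim(a)
  fwd <- c(0L, 0L, 0L); bwd <- c(0L, 0L, 0L)
  fwd[axis] <- 1L; bwd[axis] <- -1L
  g <- (shift3d(a, fwd) - shift3d(a, bwd)) / 2
  # shift3d clamps, so the border rows are already one-sided differences / 2;
  # rescale them to plain one-sided differences.
  n <- d[axis]
  if (n >= 2L) {
    sel <- function(i) switch(axis,
      `1` = g[i, , , drop = FALSE],
      `2` = g[, i, , drop = FALSE],
      `3` = g[, , i, drop = FALSE])
    asgn <- function(i, v) {
      if (axis == 1L) g[i, , ] <<- v
      else if (axis == 2L) g[, i, ] <<- v
      else g[, , i] <<- v
    }
    asgn(1L, 2 * sel(1L))
    asgn(n, 2 * sel(n))
  }
  g
}
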
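# Warping and displacement-field helpers.

#' Warp a volume through a displacement field
#'
#' Output voxel p takes the value of the input sampled at `p + phi(p)`
#' (displacements in voxel units); out-of-bounds samples are clamped to
#' the border. Trilinear interpolation is exact on grid points for the
#' zero field; nearest-neighbour is for label volumes.
#'
#' @param I a [mac_volume()] or [mac_label()].
#' @param phi a [mac_field()] on `I`'s grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return warped object of the same class as `I`.
#' @export
warp <- function(I, phi, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  a <- if (inherits(I, c("mac_volume", "mac_label"))) I$data else
    as_array3d(I)
  d <- dim(a)
  if (!identical(d, dim(phi$data)[1:3]))
    stop("field grid does not match the image grid")
  g <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  xs <- g$x + as.vector(phi$data[, , , 1])
  ys <- g$y + as.vector(phi$data[, , , 2])
  zs <- g$z + as.vector(phi$data[, , , 3])
  vals <- if (interpolation == "trilinear") trilinear3d(a * 1.0, xs, ys, zs)
          else nearest3d(a, xs, ys, zs)
  out <- array(vals, d)
  if (inherits(I, "mac_label")) {
    mac_label(array(as.integer(round(out)), d), I$spacing, I$origin)
  } else if (inherits(I, "mac_volume")) {
    mac_volume(out, I$spacing, I$origin)
  } else out
}

#' Zero displacement field on a grid
#'
#' @param dims integer length-3 grid shape.
#' @param spacing,origin grid geometry.
#' @return a [mac_field()] of zeros.
#' @export
zero_field <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  mac_field(array(0, c(dims, 3L)), spacing, origin)
}

# Gaussian-smooth each component of a displacement field.
smooth_field <- function(phi, sigma) {
  if (sigma <= 0) return(phi)
  a <- phi$data
  for (c in 1:3) a[, , , c] <- gauss_smooth3d(a[, , , c], sigma)
  mac_field(a, phi$spacing, phi$origin)
}

# Resample a displacement field onto a new grid shape by trilinear
# interpolation of each component, scaling displacements by the per-axis
# grid ratio (voxel units change with the grid).
resample_field <- function(phi, new_dims, new_spacing = NULL,
                           origin = NULL) {
  old_dims <- dim(phi$data)[1:3]
  scale <- new_dims / old_dims
  if (is.null(new_spacing)) new_spacing <- phi$spacing / scale
  if (is.null(origin)) origin <- phi$origin
  g <- expand.grid(x = 0:(new_dims[1] - 1), y = 0:(new_dims[2] - 1),
                   z = 0:(new_dims[3] - 1))
  # position on the old grid corresponding to each new voxel
  xs <- g$x / scale[1]; ys <- g$y / scale[2]; zs <- g$z / scale[3]
  out <- array(0, c(new_dims, 3L))
  for (c in 1:3) {
    comp <- trilinear3d(phi$data[, , , c], xs, ys, zs) * scale[c]
    out[, , , c] <- array(comp, new_dims)
  }
  mac_field(out, new_spacing, origin)
}

# Downsample a volume by an integer factor: Gaussian pre-smoothing at
# sigma = factor / 2 followed by decimation.
downsample_volume <- function(v, factor) {
  if (factor == 1L) return(v)
  a <- gauss_smooth3d(v$data, factor / 2)
  d <- dim(a)
  ix <- seq(1L, d[1], by = factor)
  iy <- seq(1L, d[2], by = factor)
  iz <- seq(1L, d[3], by = factor)
  mac_volume(a[ix, iy, iz, drop = FALSE], v$spacing * factor, v$origin)
}

downsample_mask_soft <- function(l, factor) {
  v <- mac_volume(soft_mask_data(l), l$spacing, l$origin)
  downsample_volume(v, factor)
}
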
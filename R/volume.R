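# Data model: volumes, label masks, displacement fields, landmark sets.
#
# Axes are ordered (x, y, z) everywhere; voxel indices are 0-based in all
# user-facing coordinates, and physical position = origin + index * spacing
# (mm). Displacement fields are stored in voxel units; conversion to mm
# happens only in metric reporting.

#' Construct a 3D scalar volume
#'
#' A volume is a 3D numeric array with a physical voxel spacing and the
#' physical position of voxel (0,0,0).
#'
#' @param data 3D numeric array (axes x, y, z).
#' @param spacing numeric length-3, voxel size in mm per axis (positive).
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return object of class `mac_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- mac_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(v$data)
#' @export
mac_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (anyNA(data))
    stop(sprintf("volume contains %d NaN/NA voxels", sum(is.na(data))))
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "mac_volume")
}

as_array3d <- function(data) {
  if (is.null(dim(data))) stop("expected 3 spatial dimensions, got a vector")
  if (length(dim(data)) != 3L)
    stop(sprintf("expected 3 spatial dimensions, got %d", length(dim(data))))
  if (any(dim(data) < 1L)) stop("all three axes must have length >= 1")
  data
}

#' Construct a label mask on a volume grid
#'
#' Integer-valued mask; 0 is background, positive integers are label ids.
#'
#' @param data 3D integer-valued array.
#' @inheritParams mac_volume
#' @return object of class `mac_label`.
#' @export
mac_label <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  if (anyNA(data)) stop("label mask contains NA voxels")
  if (any(data < 0) || any(data != round(data)))
    stop("label values must be non-negative integers")
  storage.mode(data) <- "integer"
  v <- mac_volume(array(0, dim(data)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin,
                 label_ids = sort(unique(data[data > 0L]))),
            class = "mac_label")
}

#' Construct a dense 3D displacement field
#'
#' One 3-vector per voxel, in voxel units, stored as a 4D array whose last
#' axis (length 3) holds the x/y/z components. A warp samples the moving
#' image at `p + phi(p)`.
#'
#' @param data 4D numeric array, `dim = c(nx, ny, nz, 3)`.
#' @inheritParams mac_volume
#' @return object of class `mac_field`.
#' @export
mac_field <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(data)
  if (is.null(d) || length(d) != 4L || d[4] != 3L)
    stop("displacement field must be a 4D array with last axis length 3")
  if (any(!is.finite(data)))
    stop("displacement field must be finite everywhere")
  storage.mode(data) <- "double"
  v <- mac_volume(array(0, d[1:3]), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "mac_field")
}

#' Construct a landmark set
#'
#' Physical (mm) point coordinates with unique string identifiers. Two
#' landmark sets correspond iff their id sets are equal.
#'
#' @param points data.frame or matrix with columns x, y, z (mm).
#' @param ids character vector of unique identifiers, one per point.
#' @return object of class `mac_landmarks`: data.frame with columns
#'   `id`, `x`, `y`, `z`.
#' @export
mac_landmarks <- function(points, ids = NULL) {
  points <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(points)))
    stop("points must have columns x, y, z")
  if (is.null(ids)) {
    ids <- if ("id" %in% names(points)) as.character(points$id)
           else as.character(seq_len(nrow(points)))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate landmark id")
  if (length(ids) != nrow(points)) stop("one id per point required")
  coords <- points[, c("x", "y", "z")]
  if (any(!vapply(coords, is.numeric, logical(1))) || anyNA(coords))
    stop("non-numeric landmark coordinate")
  structure(data.frame(id = ids, x = as.numeric(points$x),
                       y = as.numeric(points$y), z = as.numeric(points$z),
                       stringsAsFactors = FALSE),
            class = c("mac_landmarks", "data.frame"))
}

#' Voxel index to physical coordinate conversion
#'
#' `phys = origin + index * spacing` with 0-based indices; `voxel_to_phys`
#' and `phys_to_voxel` are exact inverses.
#'
#' @param v a `mac_volume`, `mac_label` or `mac_field` (grid provider).
#' @param idx numeric matrix (n x 3) of 0-based voxel coordinates.
#' @return numeric matrix (n x 3).
#' @export
voxel_to_phys <- function(v, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, v$spacing, `*`), 2, v$origin, `+`)
}

#' @rdname voxel_to_phys
#' @param phys numeric matrix (n x 3) of physical coordinates (mm).
#' @export
phys_to_voxel <- function(v, phys) {
  phys <- rbind(phys)
  sweep(sweep(phys, 2, v$origin, `-`), 2, v$spacing, `/`)
}

#' @export
print.mac_volume <- function(x, ...) {
  cat(sprintf("<mac_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mac_label <- function(x, ...) {
  cat(sprintf("<mac_label> %s voxels, labels {%s}\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$label_ids, collapse = ", ")))
  invisible(x)
}

#' @export
print.mac_field <- function(x, ...) {
  m <- sqrt(x$data[, , , 1]^2 + x$data[, , , 2]^2 + x$data[, , , 3]^2)
  cat(sprintf(
    "<mac_field> %s voxels, |phi| mean %.3f max %.3f (voxel units)\n",
    paste(dim(x$data)[1:3], collapse = "x"), mean(m), max(m)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- dim(a$data)[1:3]; db <- dim(b$data)[1:3]
  identical(da, db) && all(abs(a$spacing - b$spacing) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share the same grid (shape and spacing)", what))
  invisible(TRUE)
}
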
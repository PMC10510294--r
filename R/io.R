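# NIfTI and delimited-text readers/writers. Volumes, labels and fields go
# through RNifti; fields are stored as 4D NIfTI with last axis length 3.
# Only the scaling part of the NIfTI affine is honoured: volumes are
# assumed axis-aligned, and a non-diagonal rotation block triggers a
# warning (never silent reorientation).

nifti_grid <- function(img) {
  d <- dim(img)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- abs(as.numeric(pd[1:3]))
  spacing[spacing == 0] <- 1
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    rot <- xf[1:3, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(rot)))
      warning("non-diagonal NIfTI affine found; treating volume as axis-aligned")
    origin <- as.numeric(xf[1:3, 4])
  }
  list(spacing = spacing, origin = origin)
}

nifti_from <- function(data, spacing, origin) {
  img <- RNifti::asNifti(data)
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  # qform assignment resets pixdim; set it afterwards, padded to the
  # image dimensionality (fields are 4D with a unit 4th-axis step)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- c(spacing, rep(1, nd - 3L))
  img
}

#' Read a 3D volume from NIfTI
#'
#' Intensities are promoted to double; spacing is taken from the header
#' pixdim and the origin from the qform/sform offset. NaN voxels are a
#' load error.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [mac_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected 3 spatial dimensions, got %d (%s)",
                 length(dim(img)), path))
  a <- array(as.numeric(img), dim(img))
  if (anyNA(a))
    stop(sprintf("NaN voxels on load: %d affected (%s)", sum(is.na(a)), path))
  g <- nifti_grid(img)
  mac_volume(a, spacing = g$spacing, origin = g$origin)
}

#' Write a 3D volume to NIfTI
#'
#' Data are written as float32; `read_volume(write_volume(v))` reproduces
#' the data bit-identically for float32 inputs and the spacing to header
#' precision.
#'
#' @param v a [mac_volume()].
#' @param path output path (`.nii` or `.nii.gz`); parent must exist.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: %s", dirname(path)))
  img <- nifti_from(v$data, v$spacing, v$origin)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read / write a label mask as NIfTI
#'
#' Labels are stored as 32-bit integers.
#'
#' @param path NIfTI path.
#' @return a [mac_label()].
#' @export
read_label <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected 3 spatial dimensions, got %d", length(dim(img))))
  g <- nifti_grid(img)
  mac_label(array(as.integer(round(img)), dim(img)),
            spacing = g$spacing, origin = g$origin)
}

#' @rdname read_label
#' @param l a [mac_label()].
#' @export
write_label <- function(l, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: %s", dirname(path)))
  img <- nifti_from(l$data, l$spacing, l$origin)
  RNifti::writeNifti(img, path, datatype = "int")
  invisible(path)
}

#' Read / write a displacement field as 4D NIfTI
#'
#' The last axis (length 3) carries the x/y/z displacement components in
#' voxel units.
#'
#' @param path NIfTI path.
#' @return a [mac_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 3L)
    stop("expected a 4D displacement field with last axis length 3")
  g <- nifti_grid(img)
  mac_field(array(as.numeric(img), dim(img)),
            spacing = g$spacing, origin = g$origin)
}

#' @rdname read_field
#' @param phi a [mac_field()].
#' @export
write_field <- function(phi, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: %s", dirname(path)))
  img <- nifti_from(phi$data, phi$spacing, phi$origin)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read / write landmarks as CSV
#'
#' Delimited text with header `id,x,y,z`, coordinates in physical mm.
#'
#' @param path CSV path.
#' @return a [mac_landmarks()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y", "z") %in% names(df)))
    stop("landmark file must have header id,x,y,z")
  for (col in c("x", "y", "z")) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("non-numeric coordinate in column %s", col))
  }
  mac_landmarks(df, ids = df$id)
}

#' @rdname read_landmarks
#' @param lm a [mac_landmarks()].
#' @export
write_landmarks <- function(lm, path) {
  utils::write.csv(as.data.frame(unclass(lm)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
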
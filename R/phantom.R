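# Synthetic multimodal phantom generator: shared anatomy rendered under
# two modality-specific intensity mappings (one contrast-inverted for the
# lesion), a smooth ground-truth deformation, organ/lesion labels and
# corresponding landmarks. This stands in for paired clinical CT-MR
# volumes so every other module is testable without any data download;
# it emulates the *structure* of such pairs (shared geometry, monotone
# per-tissue intensity maps, modality-specific noise character), not the
# imaging physics.

#' Phantom configuration
#'
#' @param size grid shape, each axis >= 16 (default 64 x 64 x 48).
#' @param spacing voxel size in mm.
#' @param seed integer seed; the whole phantom is deterministic given it.
#' @param amplitude maximum ground-truth displacement magnitude (voxels).
#' @param sigma Gaussian smoothness of the deformation (voxels).
#' @param noise_a additive Gaussian noise level for modality A (fraction
#'   of the unit dynamic range; CT-like character).
#' @param noise_b Rician noise level for modality B (magnitude of a
#'   complex Gaussian perturbation; MR-like character).
#' @param n_landmarks number of landmarks (lesion centroid, organ
#'   centroid, organ-boundary extremal points; 2 to 14).
#' @param strict error (instead of rescale + warning) if the requested
#'   deformation would fold.
#' @return object of class `mac_phantom_config`.
#' @export
phantom_config <- function(size = c(64L, 64L, 48L), spacing = c(1, 1, 1),
                           seed = 1L, amplitude = 4, sigma = 6,
                           noise_a = 0.02, noise_b = 0.04,
                           n_landmarks = 8L, strict = FALSE) {
  size <- as.integer(size)
  if (length(size) != 3L || any(size < 16L))
    stop("size must be 3 axes of at least 16 voxels")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (n_landmarks < 2L || n_landmarks > 14L)
    stop("n_landmarks must be between 2 and 14")
  structure(list(size = size, spacing = as.numeric(spacing),
                 seed = as.integer(seed), amplitude = amplitude,
                 sigma = sigma, noise_a = noise_a, noise_b = noise_b,
                 n_landmarks = as.integer(n_landmarks), strict = strict),
            class = "mac_phantom_config")
}

#' Generate a smooth, fold-free ground-truth deformation
#'
#' I.i.d. Gaussian noise per component, Gaussian-smoothed with `sigma`,
#' rescaled so the maximum displacement magnitude equals `amplitude`, and
#' attenuated to zero at the volume boundary by a cosine taper over 4
#' voxels. If the result folds (negative Jacobian determinant anywhere),
#' it is rescaled down by 30% steps with a warning (error in strict
#' mode). Deterministic given the seed.
#'
#' @param cfg a [phantom_config()].
#' @return a [mac_field()] with zero folding count.
#' @export
generate_deformation <- function(cfg) {
  d <- cfg$size
  if (cfg$amplitude == 0)
    return(zero_field(d, cfg$spacing))
  set.seed(cfg$seed + 1L)
  a <- array(stats::rnorm(prod(d) * 3), c(d, 3L))
  # periodic FFT smoothing keeps the noise field statistics stationary up
  # to the border (spatial edge replication would inflate boundary
  # variance and let the rescale step under-size the interior); the taper
  # below removes the periodic seam
  for (c in 1:3) a[, , , c] <- fft_smooth3d(a[, , , c], cfg$sigma)
  taper1 <- function(n) {
    i <- 0:(n - 1)
    dd <- pmin(i, n - 1 - i, 4)
    0.5 * (1 - cos(pi * dd / 4))
  }
  w <- outer(outer(taper1(d[1]), taper1(d[2])), taper1(d[3]))
  for (c in 1:3) a[, , , c] <- a[, , , c] * w
  # rescale after the taper so the delivered field really attains the
  # configured maximum displacement (edge replication inflates the
  # smoothed noise near the border, which the taper then removes)
  mag <- sqrt(a[, , , 1]^2 + a[, , , 2]^2 + a[, , , 3]^2)
  a <- a * (cfg$amplitude / max(mag))
  phi <- mac_field(a, cfg$spacing)
  rep_j <- jacobian_report(phi)
  tries <- 0L
  while (rep_j$folding_count > 0 && tries < 10L) {
    if (cfg$strict)
      stop("requested amplitude/sigma produce a folding deformation")
    warning("deformation folds; rescaling amplitude down by 30%")
    phi <- mac_field(phi$data * 0.7, cfg$spacing)
    rep_j <- jacobian_report(phi)
    tries <- tries + 1L
  }
  phi
}

.phantom_taper_tanh <- function(t, slope) tanh(slope * t)

# Tissue classes: 0 background, 1 body, 2 spine-like rod, 3 vessel-like
# blobs, 4 organ, 5 lesion. Intensity = base[class] + gain[class] *
# tanh(slope * texture): monotone per class, with the lesion gain sign
# flipped between modalities (contrast inversion).
.phantom_base_a <- c(0.02, 0.35, 0.90, 0.55, 0.60, 0.30)
.phantom_gain_a <- c(0.01, 0.04, 0.02, 0.03, 0.05, 0.08)
.phantom_base_b <- c(0.05, 0.55, 0.25, 0.35, 0.35, 0.80)
.phantom_gain_b <- c(0.01, 0.05, -0.02, 0.04, 0.06, -0.12)

.phantom_geometry <- function(cfg) {
  set.seed(cfg$seed)
  d <- cfg$size; sp <- cfg$spacing
  ext <- (d - 1) * sp
  xs <- (0:(d[1] - 1)) * sp[1]
  ys <- (0:(d[2] - 1)) * sp[2]
  zs <- (0:(d[3] - 1)) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  ctr <- ext / 2

  cls <- array(0L, d)
  # body
  brad <- 0.46 * ext
  body <- ((X - ctr[1]) / brad[1])^2 + ((Y - ctr[2]) / brad[2])^2 +
    ((Z - ctr[3]) / brad[3])^2 <= 1
  cls[body] <- 1L
  # spine-like rod along z, posterior
  sc <- c(0.5, 0.80) * ext[1:2]
  spine <- ((X - sc[1])^2 + (Y - sc[2])^2) <= (0.055 * min(ext))^2 & body
  cls[spine] <- 2L
  # two vessel-like blobs
  for (i in 1:2) {
    vc <- ctr + (stats::runif(3) - 0.5) * 0.5 * ext
    vr <- (0.035 + 0.01 * stats::runif(1)) * min(ext)
    ves <- ((X - vc[1])^2 + (Y - vc[2])^2 + (Z - vc[3])^2) <= vr^2 & body
    cls[ves] <- 3L
  }
  # lobulated organ
  oc <- ctr + c(0.06, -0.05, 0.02) * ext
  orad <- c(0.27, 0.21, 0.27) * ext
  dx <- (X - oc[1]) / orad[1]
  dy <- (Y - oc[2]) / orad[2]
  dz <- (Z - oc[3]) / orad[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  th <- atan2(dy, dx)
  ps <- acos(dz / pmax(r, 1e-9))
  lob <- stats::rnorm(3, 0, 1)
  shape <- 1 + 0.06 * lob[1] * sin(2 * th) * sin(ps) +
    0.05 * lob[2] * cos(3 * th) * sin(ps)^2 +
    0.04 * lob[3] * cos(2 * ps)
  organ <- r <= shape
  cls[organ] <- 4L
  # lesion inside the organ
  ldir <- stats::rnorm(3); ldir <- ldir / sqrt(sum(ldir^2))
  lc <- oc + 0.35 * orad * ldir
  lrad <- 0.09 * min(ext)
  lesion <- ((X - lc[1])^2 + (Y - lc[2])^2 + (Z - lc[3])^2) <= lrad^2
  if (any(lesion & !organ))
    stop("lesion does not fit inside the organ at the requested size")
  cls[lesion] <- 5L

  # shared smooth texture field, unit variance
  tex <- gauss_smooth3d(array(stats::rnorm(prod(d)), d), 3)
  tex <- (tex - mean(tex)) / stats::sd(tex)

  list(cls = cls, tex = tex, organ_centre = oc, lesion_centre = lc)
}

.phantom_render <- function(cls, tex, base, gain, slope) {
  array(base[cls + 1L] + gain[cls + 1L] * tanh(slope * tex), dim(cls))
}

.phantom_landmarks_a <- function(cls, cfg) {
  sp <- cfg$spacing
  vox_of <- function(m) which(m, arr.ind = TRUE) - 1L
  lesion <- vox_of(cls == 5L)
  surf <- surface_voxels(cls >= 4L)
  # lesion centroid plus organ-boundary extremal points (axis extremes,
  # then diagonal extremes when more landmarks are requested); interior
  # points away from any boundary carry no localisable image structure
  # and are not used
  pts <- rbind(colMeans(lesion))
  ids <- "lesion_centre"
  for (axis in 1:3) {
    for (s in c(1, -1)) {
      i <- which.max(s * surf[, axis])
      pts <- rbind(pts, surf[i, ])
      ids <- c(ids, sprintf("organ_%s%s", c("x", "y", "z")[axis],
                            if (s > 0) "max" else "min"))
    }
  }
  # diagonal extremal points if more are requested
  diags <- rbind(c(1, 1, 0), c(1, -1, 0), c(0, 1, 1), c(0, 1, -1),
                 c(1, 0, 1), c(1, 0, -1))
  for (k in seq_len(nrow(diags))) {
    if (nrow(pts) >= cfg$n_landmarks) break
    i <- which.max(surf %*% diags[k, ])
    pts <- rbind(pts, surf[i, ])
    ids <- c(ids, sprintf("organ_diag%d", k))
  }
  n <- min(cfg$n_landmarks, nrow(pts))
  mac_landmarks(data.frame(x = pts[1:n, 1] * sp[1],
                           y = pts[1:n, 2] * sp[2],
                           z = pts[1:n, 3] * sp[3]),
                ids = ids[1:n])
}

# Invert the displacement field at given a-frame voxel positions by
# fixed-point iteration: find p with p + phi(p) = q.
.invert_field_at <- function(phi, q_vox, iters = 40L) {
  p <- q_vox
  for (i in seq_len(iters)) {
    disp <- sapply(1:3, function(c)
      trilinear3d(phi$data[, , , c], p[, 1], p[, 2], p[, 3]))
    disp <- matrix(disp, ncol = 3)
    p <- q_vox - disp
  }
  p
}

#' Generate a multimodal phantom case
#'
#' Builds a shared anatomy (body, spine-like and vessel-like background
#' structures, a lobulated organ with an interior lesion), renders
#' modality A in the undeformed frame with a monotone per-class intensity
#' map plus Gaussian noise, renders modality B in the frame deformed by
#' the ground-truth field with a different monotone per-class map whose
#' lesion contrast is inverted (lesion dark in A, bright in B) plus
#' Rician-like noise, and derives organ/lesion labels and corresponding
#' landmarks for both frames. Landmarks in the deformed frame are
#' obtained by fixed-point inversion of the ground-truth field, so
#' mapping a B landmark through the field lands on its A partner.
#'
#' @param cfg a [phantom_config()].
#' @return object of class `mac_phantom`: list with `vol_a`, `vol_b`,
#'   `label_organ_a`, `label_lesion_a`, `label_organ_b`,
#'   `label_lesion_b`, `phi_true` (mapping b-frame positions into the
#'   a-frame), `landmarks_a`, `landmarks_b`, `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  geo <- .phantom_geometry(cfg)
  d <- cfg$size; sp <- cfg$spacing
  set.seed(cfg$seed + 2L)
  noise_a <- array(stats::rnorm(prod(d), 0, cfg$noise_a), d)
  n1 <- array(stats::rnorm(prod(d), 0, cfg$noise_b), d)
  n2 <- array(stats::rnorm(prod(d), 0, cfg$noise_b), d)

  a0 <- .phantom_render(geo$cls, geo$tex, .phantom_base_a,
                        .phantom_gain_a, 1.0)
  vol_a <- mac_volume(a0 + noise_a, sp)

  phi_true <- generate_deformation(cfg)

  cls_lab <- mac_label(geo$cls, sp)
  cls_b <- warp(cls_lab, phi_true, interpolation = "nearest")
  tex_b <- warp(mac_volume(geo$tex, sp), phi_true)$data
  b0 <- .phantom_render(cls_b$data, tex_b, .phantom_base_b,
                        .phantom_gain_b, 1.2)
  vol_b <- mac_volume(sqrt((b0 + n1)^2 + n2^2), sp)

  label_organ_a <- mac_label(array(as.integer(geo$cls >= 4L), d), sp)
  label_lesion_a <- mac_label(array(as.integer(geo$cls == 5L), d), sp)
  label_organ_b <- mac_label(array(as.integer(cls_b$data >= 4L), d), sp)
  label_lesion_b <- mac_label(array(as.integer(cls_b$data == 5L), d), sp)

  landmarks_a <- .phantom_landmarks_a(geo$cls, cfg)
  qa_vox <- as.matrix(landmarks_a[, c("x", "y", "z")])
  qa_vox <- sweep(qa_vox, 2, sp, `/`)
  qb_vox <- .invert_field_at(phi_true, qa_vox)
  landmarks_b <- mac_landmarks(
    data.frame(x = qb_vox[, 1] * sp[1], y = qb_vox[, 2] * sp[2],
               z = qb_vox[, 3] * sp[3]),
    ids = landmarks_a$id)

  structure(list(vol_a = vol_a, vol_b = vol_b,
                 label_organ_a = label_organ_a,
                 label_lesion_a = label_lesion_a,
                 label_organ_b = label_organ_b,
                 label_lesion_b = label_lesion_b,
                 phi_true = phi_true,
                 landmarks_a = landmarks_a, landmarks_b = landmarks_b,
                 config = cfg),
            class = "mac_phantom")
}

#' @export
print.mac_phantom <- function(x, ...) {
  cat(sprintf(
    "<mac_phantom> %s voxels, seed %d, amplitude %.2g voxels, %d landmarks\n",
    paste(x$config$size, collapse = "x"), x$config$seed,
    x$config$amplitude, nrow(x$landmarks_a)))
  invisible(x)
}

phantom_file_names <- c(
  "vol_a.nii.gz", "vol_b.nii.gz",
  "label_organ_a.nii.gz", "label_lesion_a.nii.gz",
  "label_organ_b.nii.gz", "label_lesion_b.nii.gz",
  "phi_true.nii.gz", "landmarks_a.csv", "landmarks_b.csv")

#' Write / read a phantom case to a directory
#'
#' Writes the two volumes, four label masks, the ground-truth field and
#' the two landmark tables, plus a `manifest.json` holding the full
#' configuration (sufficient to regenerate the case bit-identically).
#'
#' @param case a `mac_phantom`.
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$vol_a, file.path(dir, "vol_a.nii.gz"))
  write_volume(case$vol_b, file.path(dir, "vol_b.nii.gz"))
  write_label(case$label_organ_a, file.path(dir, "label_organ_a.nii.gz"))
  write_label(case$label_lesion_a, file.path(dir, "label_lesion_a.nii.gz"))
  write_label(case$label_organ_b, file.path(dir, "label_organ_b.nii.gz"))
  write_label(case$label_lesion_b, file.path(dir, "label_lesion_b.nii.gz"))
  write_field(case$phi_true, file.path(dir, "phi_true.nii.gz"))
  write_landmarks(case$landmarks_a, file.path(dir, "landmarks_a.csv"))
  write_landmarks(case$landmarks_b, file.path(dir, "landmarks_b.csv"))
  manifest <- list(generator = "macmind::generate_phantom",
                   version = as.character(utils::packageVersion("macmind")),
                   config = unclass(case$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @return `read_phantom` returns the `mac_phantom` reassembled from the
#'   files on disk.
#' @export
read_phantom <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(phantom_config, manifest$config[
    setdiff(names(manifest$config), character(0))])
  structure(list(
    vol_a = read_volume(file.path(dir, "vol_a.nii.gz")),
    vol_b = read_volume(file.path(dir, "vol_b.nii.gz")),
    label_organ_a = read_label(file.path(dir, "label_organ_a.nii.gz")),
    label_lesion_a = read_label(file.path(dir, "label_lesion_a.nii.gz")),
    label_organ_b = read_label(file.path(dir, "label_organ_b.nii.gz")),
    label_lesion_b = read_label(file.path(dir, "label_lesion_b.nii.gz")),
    phi_true = read_field(file.path(dir, "phi_true.nii.gz")),
    landmarks_a = read_landmarks(file.path(dir, "landmarks_a.csv")),
    landmarks_b = read_landmarks(file.path(dir, "landmarks_b.csv")),
    config = cfg), class = "mac_phantom")
}
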
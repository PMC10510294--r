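# Evaluation metric panel: mutual information, SSIM, Dice, 95% Hausdorff
# distance, landmark target registration error, absolute relative volume
# difference and volumetric overlap error.

#' Mutual information between two volumes
#'
#' MI from a joint histogram with `bins` equal-width bins per image over
#' each image's min-max range, natural logarithm, zero-probability cells
#' skipped. `MI(I, I)` equals the marginal entropy of `I` under the same
#' binning. A constant image has a single-bin degenerate histogram and
#' yields 0 with a warning.
#'
#' @param a,b [mac_volume()]s (or 3D arrays) on the same grid.
#' @param bins number of histogram bins per image.
#' @return MI in nats (non-negative up to float error).
#' @export
mutual_information <- function(a, b, bins = 32L) {
  x <- as.vector(as_volume_data(a))
  y <- as.vector(as_volume_data(b))
  if (length(x) != length(y)) stop("volumes must share the grid")
  rx <- range(x); ry <- range(y)
  if (rx[1] == rx[2] || ry[1] == ry[2]) {
    warning("constant image: mutual information defined as 0")
    return(0)
  }
  bx <- pmin(1L + as.integer((x - rx[1]) / (rx[2] - rx[1]) * bins), bins)
  by <- pmin(1L + as.integer((y - ry[1]) / (ry[2] - ry[1]) * bins), bins)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  px <- tabulate(bx, nbins = bins) / length(x)
  py <- tabulate(by, nbins = bins) / length(y)
  pxy_ind <- as.vector(outer(px, py))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / pxy_ind[nz]))
}

#' Marginal entropy of a volume under equal-width binning
#'
#' @inheritParams mutual_information
#' @return entropy in nats.
#' @export
shannon_entropy <- function(a, bins = 32L) {
  x <- as.vector(as_volume_data(a))
  rx <- range(x)
  if (rx[1] == rx[2]) return(0)
  bx <- pmin(1L + as.integer((x - rx[1]) / (rx[2] - rx[1]) * bins), bins)
  px <- tabulate(bx, nbins = bins) / length(x)
  nz <- px > 0
  -sum(px[nz] * log(px[nz]))
}

#' Global structural similarity (SSIM)
#'
#' Whole-volume SSIM from global means, variances and covariance, after
#' min-max normalizing each image to [0, 1]; stabilizers
#' `c1 = 0.01^2`, `c2 = 0.03^2` on that range. The default is the
#' standard product form
#' `(2*mu_a*mu_b + c1)(2*cov + c2) / ((mu_a^2 + mu_b^2 + c1)(var_a + var_b + c2))`,
#' which attains exactly 1 on identical images. `paper_literal = TRUE`
#' instead evaluates a sum-form numerator
#' `((2*mu_a*mu_b + c1) + (2*cov + c2))` over the same denominator — a
#' variant that appears in print in parts of the literature but does not
#' satisfy SSIM(I, I) = 1; it is kept inspectable, not used by default.
#'
#' @param a,b [mac_volume()]s (or 3D arrays) on the same grid.
#' @param c1,c2 stabilizing constants (on the [0, 1] intensity range).
#' @param paper_literal use the sum-form numerator as printed in some
#'   sources.
#' @return SSIM scalar (1 for identical images in the default form).
#' @export
ssim <- function(a, b, c1 = 0.01^2, c2 = 0.03^2, paper_literal = FALSE) {
  x <- as.vector(as_volume_data(a))
  y <- as.vector(as_volume_data(b))
  if (length(x) != length(y)) stop("volumes must share the grid")
  norm01 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(0, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }
  x <- norm01(x); y <- norm01(y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  denom <- (mx^2 + my^2 + c1) * (vx + vy + c2)
  if (paper_literal) ((2 * mx * my + c1) + (2 * cxy + c2)) / denom
  else (2 * mx * my + c1) * (2 * cxy + c2) / denom
}

mask_of <- function(x, label_id = NULL) {
  a <- if (inherits(x, c("mac_label", "mac_volume"))) x$data else x
  if (is.null(label_id)) a > 0 else a == label_id
}

#' Dice similarity coefficient (percent)
#'
#' `100 * 2|A n B| / (|A| + |B|)` for the selected label (any positive
#' label by default). Two empty masks score 100 with a warning; in strict
#' mode an absent label is an error instead.
#'
#' @param a,b [mac_label()]s (or arrays) on the same grid.
#' @param label_id evaluate this label id only (default: any nonzero).
#' @param strict error when the label is absent from both inputs.
#' @return percent in [0, 100].
#' @export
dsc <- function(a, b, label_id = NULL, strict = FALSE) {
  ma <- mask_of(a, label_id); mb <- mask_of(b, label_id)
  if (!identical(dim(ma), dim(mb))) stop("masks must share the grid")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) {
    if (strict) stop("label absent from both inputs")
    warning("both masks empty: DSC defined as 100")
    return(100)
  }
  100 * 2 * sum(ma & mb) / (sa + sb)
}

#' Volumetric overlap error (percent)
#'
#' `(1 - |A n B| / |A u B|) * 100`.
#'
#' @inheritParams dsc
#' @return percent in [0, 100].
#' @export
voe <- function(a, b, label_id = NULL) {
  ma <- mask_of(a, label_id); mb <- mask_of(b, label_id)
  if (!identical(dim(ma), dim(mb))) stop("masks must share the grid")
  uni <- sum(ma | mb)
  if (uni == 0) stop("both masks empty")
  (1 - sum(ma & mb) / uni) * 100
}

#' Absolute relative volume difference (percent)
#'
#' `|V_seg / V_gt - 1| * 100` with voxel counts; not symmetric — the
#' second argument is the ground truth.
#'
#' @param seg segmentation mask.
#' @param gt ground-truth mask (nonempty).
#' @inheritParams dsc
#' @return percent (>= 0, unbounded above).
#' @export
rvd_abs <- function(seg, gt, label_id = NULL) {
  ms <- mask_of(seg, label_id); mg <- mask_of(gt, label_id)
  if (!identical(dim(ms), dim(mg))) stop("masks must share the grid")
  vg <- sum(mg)
  if (vg == 0) stop("empty ground-truth mask")
  abs(sum(ms) / vg - 1) * 100
}

# Surface voxels of a binary mask: mask voxels with at least one
# background 6-neighbour (voxels on the volume border count, the outside
# being background). Returns an n x 3 matrix of 0-based voxel indices.
surface_voxels <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(m & !interior, arr.ind = TRUE) - 1L
}

# Minimum Euclidean distance (mm) from each point of `from` to the point
# set `to`, both n x 3 voxel-index matrices; chunked to bound memory.
.surface_min_dist <- function(from, to, spacing, chunk = 512L) {
  fp <- sweep(from, 2, spacing, `*`)
  tp <- sweep(to, 2, spacing, `*`)
  n <- nrow(fp)
  out <- numeric(n)
  t2 <- rowSums(tp^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    f <- fp[s:e, , drop = FALSE]
    d2 <- outer(rowSums(f^2), t2, `+`) - 2 * f %*% t(tp)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95th-percentile symmetric surface distance (mm)
#'
#' Surfaces are the mask voxels with at least one background 6-neighbour;
#' surface-to-surface Euclidean distances are computed in mm via the
#' voxel spacing, pooled over both directions, and summarized by the
#' linear-interpolation 95th percentile. Symmetric in its arguments.
#'
#' @param a,b nonempty [mac_label()]s (or arrays) on the same grid.
#' @param spacing voxel spacing in mm (taken from `a` when available).
#' @inheritParams dsc
#' @return distance in mm.
#' @export
hd95 <- function(a, b, spacing = NULL, label_id = NULL) {
  if (is.null(spacing))
    spacing <- if (inherits(a, c("mac_label", "mac_volume"))) a$spacing
               else c(1, 1, 1)
  ma <- mask_of(a, label_id); mb <- mask_of(b, label_id)
  if (!identical(dim(ma), dim(mb))) stop("masks must share the grid")
  if (sum(ma) == 0 || sum(mb) == 0) stop("empty mask in Hd95")
  sa <- surface_voxels(ma); sb <- surface_voxels(mb)
  pooled <- c(.surface_min_dist(sa, sb, spacing),
              .surface_min_dist(sb, sa, spacing))
  as.numeric(stats::quantile(pooled, 0.95, type = 7))
}

#' Target registration error of corresponding landmarks (mm)
#'
#' Each source landmark is mapped through the displacement field — the
#' field is interpolated trilinearly at the landmark's (fractional) voxel
#' position, the displacement added in voxel units and converted back to
#' mm — and compared with its identically-identified partner in the
#' target set by Euclidean distance. With a zero field this is the plain
#' distance between partners.
#'
#' In a registration with `warped(p) = moving(p + phi(p))`, `phi` lives
#' on the fixed grid and maps fixed-frame positions into the moving
#' frame, so `source_lms` are the fixed-image landmarks and `target_lms`
#' the moving-image ones.
#'
#' @param target_lms,source_lms corresponding [mac_landmarks()] (equal id
#'   sets).
#' @param phi a [mac_field()] (its grid converts mm to voxel positions).
#' @return data.frame with columns `id` and `tre_mm`, one row per
#'   landmark, ordered as `source_lms`.
#' @export
tre <- function(target_lms, source_lms, phi) {
  if (!setequal(target_lms$id, source_lms$id))
    stop("landmark sets do not correspond (id sets differ)")
  tgt <- target_lms[match(source_lms$id, target_lms$id), ]
  src_vox <- phys_to_voxel(phi, as.matrix(source_lms[, c("x", "y", "z")]))
  d <- dim(phi$data)[1:3]
  if (any(src_vox < -0.5) || any(sweep(src_vox, 2, d - 0.5, `>`)))
    stop("landmark outside the field domain")
  disp <- sapply(1:3, function(c)
    trilinear3d(phi$data[, , , c], src_vox[, 1], src_vox[, 2],
                src_vox[, 3]))
  disp <- matrix(disp, ncol = 3)
  mapped_vox <- src_vox + disp
  mapped_mm <- voxel_to_phys(phi, mapped_vox)
  delta <- mapped_mm - as.matrix(tgt[, c("x", "y", "z")])
  data.frame(id = source_lms$id, tre_mm = sqrt(rowSums(delta^2)),
             stringsAsFactors = FALSE)
}

#' Full evaluation panel for a registration result
#'
#' Bundles MI and SSIM over the whole image pair, per-label DSC, Hd95,
#' RVDabs and VOE, and landmark TRE when landmarks and a field are given.
#'
#' @param fixed,warped [mac_volume()]s on the same grid.
#' @param fixed_label,warped_label optional [mac_label()]s.
#' @param target_lms,source_lms optional corresponding landmark sets (see
#'   [tre()]).
#' @param phi optional [mac_field()] for the TRE.
#' @param mi_bins histogram bins for MI.
#' @return object of class `mac_metric_panel` (a list; `as.data.frame`
#'   gives one row per metric).
#' @export
metric_panel <- function(fixed, warped, fixed_label = NULL,
                         warped_label = NULL, target_lms = NULL,
                         source_lms = NULL, phi = NULL, mi_bins = 32L) {
  out <- list(mi = mutual_information(fixed, warped, mi_bins),
              ssim = ssim(fixed, warped))
  if (!is.null(fixed_label) && !is.null(warped_label)) {
    out$dsc_percent <- dsc(fixed_label, warped_label)
    out$hd95_mm <- hd95(fixed_label, warped_label)
    out$rvd_abs_percent <- rvd_abs(warped_label, fixed_label)
    out$voe_percent <- voe(fixed_label, warped_label)
  }
  if (!is.null(target_lms) && !is.null(source_lms) && !is.null(phi)) {
    t <- tre(target_lms, source_lms, phi)
    out$tre_mm <- t$tre_mm
    out$tre_mean_mm <- mean(t$tre_mm)
    out$tre_ids <- t$id
  }
  structure(out, class = "mac_metric_panel")
}

#' @export
print.mac_metric_panel <- function(x, ...) {
  cat("<mac_metric_panel>\n")
  for (k in setdiff(names(x), c("tre_mm", "tre_ids")))
    cat(sprintf("  %-16s %.4f\n", k, x[[k]]))
  if (!is.null(x$tre_mm))
    cat(sprintf("  per-landmark TRE: %s\n",
                paste(sprintf("%.2f", x$tre_mm), collapse = ", ")))
  invisible(x)
}
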
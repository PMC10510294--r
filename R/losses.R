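# Registration losses: descriptor similarity, diffusion smoothness and
# soft-Dice label consistency, plus the weighted total used by the
# optimizer. All are pure functions of their inputs.

#' Registration loss configuration
#'
#' Non-negative weights of the three loss terms. The total is
#' `E = lambda_sim * E_sim + lambda_label * E_label + lambda_smo * E_smo`;
#' `lambda_sim` defaults to 1 so the unweighted similarity reading is the
#' baseline, while the shipped default configuration file uses the
#' weights (20, 2, 0.5).
#'
#' @param lambda_sim,lambda_label,lambda_smo non-negative weights.
#' @param descriptor a [descriptor_config()] used when the loss is
#'   evaluated from raw volumes.
#' @return object of class `mac_loss_config`.
#' @export
reg_loss_config <- function(lambda_sim = 1, lambda_label = 2,
                            lambda_smo = 0.5,
                            descriptor = descriptor_config()) {
  w <- c(lambda_sim, lambda_label, lambda_smo)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative")
  structure(list(lambda_sim = lambda_sim, lambda_label = lambda_label,
                 lambda_smo = lambda_smo, descriptor = descriptor),
            class = "mac_loss_config")
}

#' Descriptor similarity loss
#'
#' Mean over voxels of the squared channel-vector difference between two
#' feature maps on the same grid (sum over channels, mean over the voxel
#' domain). Zero iff the maps are identical; symmetric in its arguments.
#'
#' @param feat_fixed,feat_warped `mac_featmap`s on identical grids with
#'   identical channel metadata.
#' @return non-negative scalar.
#' @export
sim_loss <- function(feat_fixed, feat_warped) {
  da <- dim(feat_fixed$data); db <- dim(feat_warped$data)
  if (!identical(da, db))
    stop("feature maps must share grid and channel count")
  if (!identical(dim(feat_fixed$channel_meta), dim(feat_warped$channel_meta)))
    stop("feature maps must share channel metadata")
  nvox <- prod(da[1:3])
  sum((feat_fixed$data - feat_warped$data)^2) / nvox
}

#' Diffusion smoothness loss
#'
#' Sum over voxels of the squared forward-difference spatial gradients of
#' all three displacement components, in voxel units; differences at the
#' far boundary are taken as zero.
#'
#' @param phi a [mac_field()].
#' @return non-negative scalar.
#' @export
smoothness_loss <- function(phi) {
  a <- phi$data
  d <- dim(a)[1:3]
  total <- 0
  for (comp in 1:3) {
    u <- a[, , , comp]
    for (axis in 1:3) {
      if (d[axis] < 2L) next
      fw <- c(0L, 0L, 0L); fw[axis] <- 1L
      g <- shift3d(u, fw) - u
      # shift3d clamps, so the far-boundary slice difference is already 0
      total <- total + sum(g^2)
    }
  }
  total
}

#' Soft Dice label loss
#'
#' `1 - softDice` with `softDice = (2 * sum(a*b) + eps) / (sum(a) +
#' sum(b) + eps)` and `eps = 1e-6`; accepts binary or soft (interpolated)
#' masks on the same grid. 0 for identical masks, ~1 for disjoint ones.
#'
#' @param l_fixed,l_warped `mac_label`s, `mac_volume`s or numeric arrays
#'   of membership values in [0, 1].
#' @param eps smoothing constant.
#' @return scalar in [0, 1].
#' @export
dice_label_loss <- function(l_fixed, l_warped, eps = 1e-6) {
  a <- soft_mask_data(l_fixed)
  b <- soft_mask_data(l_warped)
  if (!identical(dim(a), dim(b))) stop("label masks must share the grid")
  1 - (2 * sum(a * b) + eps) / (sum(a) + sum(b) + eps)
}

soft_mask_data <- function(x) {
  if (inherits(x, c("mac_label", "mac_volume"))) x <- x$data
  as_array3d(x) * 1.0
}

#' Segmentation consistency loss
#'
#' Two branches depending on whether ground-truth labels exist: without
#' them, the Dice loss between the fixed-frame prediction and the warped
#' moving-frame prediction (cross-modality consistency through the
#' deformation); with them, the sum of the two prediction-vs-ground-truth
#' Dice losses.
#'
#' @param lseg_f,lseg_m predicted masks for the fixed / moving frames.
#' @param phi displacement field on the fixed grid (required in the
#'   unlabeled branch, used to warp `lseg_m`).
#' @param lgt_f,lgt_m optional ground-truth masks.
#' @return non-negative scalar.
#' @export
seg_consistency_loss <- function(lseg_f, lseg_m, phi = NULL,
                                 lgt_f = NULL, lgt_m = NULL) {
  if (!is.null(lgt_f) && !is.null(lgt_m)) {
    return(dice_label_loss(lseg_f, lgt_f) + dice_label_loss(lseg_m, lgt_m))
  }
  if (is.null(phi))
    stop("phi is required when no ground-truth labels are given")
  warped <- warp_mask_soft(lseg_m, phi)
  dice_label_loss(lseg_f, warped)
}

# Warp a (possibly integer) mask as a soft membership via trilinear
# interpolation; used for loss purposes (nearest-neighbour is used for
# final reported masks).
warp_mask_soft <- function(mask, phi) {
  a <- soft_mask_data(mask)
  grid <- grid_of(if (inherits(mask, c("mac_label", "mac_volume"))) mask
                  else phi)
  w <- warp(mac_volume(a, grid$spacing, grid$origin), phi,
            interpolation = "trilinear")
  w$data
}

#' Evaluate the full registration loss
#'
#' Computes the descriptor similarity term from the macMIND maps of the
#' fixed and warped images, the smoothness term from the field, and
#' optionally the label Dice term, and combines them with the configured
#' weights.
#'
#' @param fixed fixed image ([mac_volume()]).
#' @param warped warped moving image ([mac_volume()]).
#' @param phi the displacement field that produced `warped`.
#' @param cfg a [reg_loss_config()].
#' @param fixed_label,warped_label optional masks for the label term.
#' @param feat_fixed optional precomputed feature map of `fixed`.
#' @return a `mac_loss_report`: list with `e_sim`, `e_label`, `e_smo`,
#'   `e_total` and the per-term weighted contributions, satisfying
#'   `e_total = lambda_sim*e_sim + lambda_label*e_label + lambda_smo*e_smo`.
#' @export
evaluate_reg_loss <- function(fixed, warped, phi, cfg = reg_loss_config(),
                              fixed_label = NULL, warped_label = NULL,
                              feat_fixed = NULL) {
  if (is.null(feat_fixed)) feat_fixed <- macmind(fixed, cfg$descriptor)
  feat_warped <- macmind(warped, cfg$descriptor)
  e_sim <- sim_loss(feat_fixed, feat_warped)
  e_smo <- smoothness_loss(phi)
  e_label <- if (!is.null(fixed_label) && !is.null(warped_label))
    dice_label_loss(fixed_label, warped_label) else 0
  loss_report(e_sim, e_label, e_smo, cfg)
}

loss_report <- function(e_sim, e_label, e_smo, cfg) {
  terms <- c(sim = cfg$lambda_sim * e_sim,
             label = cfg$lambda_label * e_label,
             smo = cfg$lambda_smo * e_smo)
  if (any(!is.finite(terms)))
    stop(sprintf("non-finite loss term: %s",
                 paste(names(terms)[!is.finite(terms)], collapse = ", ")))
  structure(list(e_sim = e_sim, e_label = e_label, e_smo = e_smo,
                 weighted = terms, e_total = sum(terms),
                 lambda = c(sim = cfg$lambda_sim, label = cfg$lambda_label,
                            smo = cfg$lambda_smo)),
            class = "mac_loss_report")
}

#' @export
print.mac_loss_report <- function(x, ...) {
  cat(sprintf(
    "<mac_loss_report> total %.6g (sim %.6g, label %.6g, smo %.6g)\n",
    x$e_total, x$e_sim, x$e_label, x$e_smo))
  invisible(x)
}
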
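# Self-similarity descriptors: patch SSD maps, MIND, the 18-connection
# self-similarity context (SSC), its multi-scale combination (msSSC) and
# the log-polar aggregated macMIND feature map.
#
# All maps are computed with the shift-and-convolve scheme: the SSD
# between the patch at p + o_i and the patch at p + o_j equals a uniform
# box filter applied to the squared difference of two shifted copies of
# the image, so no per-voxel patch loop is needed. Matching naive
# per-voxel implementations live in naive.R and are used as oracles in
# the tests.

#' Descriptor configuration
#'
#' Bundles the tunable parameters of the descriptor family: the base patch
#' distance `L`, the patch edge `R1` used for the patch SSD, the
#' aggregation patch edge `R2`, the number of sampling scales `K` with
#' per-scale weights `alphas` (normalized to sum 1 on construction), the
#' log-polar bin counts `Na`/`Nr`/`Nh` and the relative floor `eps_rel`
#' for the normalizing denominator on flat image regions.
#'
#' The default weights are `alphas = c(0.7, 0.3)`; the weighting of the
#' two scales is the single most influential choice (see the package
#' vignette for the reasoning and the alternative `c(0.3, 0.7)` ordering).
#'
#' @param L base patch distance in voxels (scale k samples at `k * L`).
#' @param R1 SSD patch edge length in voxels (odd).
#' @param R2 aggregation patch edge length in voxels (odd).
#' @param K number of scales (>= 1).
#' @param alphas length-`K` non-negative scale weights.
#' @param Na,Nr,Nh angular / radial / height bin counts.
#' @param eps_rel relative denominator floor (of the global mean).
#' @return object of class `mac_descriptor_config`.
#' @export
descriptor_config <- function(L = 2L, R1 = 5L, R2 = 5L, K = 2L,
                              alphas = c(0.7, 0.3),
                              Na = 8L, Nr = 2L, Nh = 2L,
                              eps_rel = 1e-6) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  alphas <- as.numeric(alphas)
  if (length(alphas) != K) stop("length(alphas) must equal K")
  if (any(alphas < 0) || sum(alphas) <= 0)
    stop("alphas must be non-negative with positive sum")
  alphas <- alphas / sum(alphas)
  if (R1 %% 2L != 1L || R2 %% 2L != 1L) stop("R1 and R2 must be odd")
  if (L < 1L) stop("L must be >= 1")
  structure(list(L = as.integer(L), R1 = as.integer(R1), R2 = as.integer(R2),
                 K = K, alphas = alphas,
                 Na = as.integer(Na), Nr = as.integer(Nr),
                 Nh = as.integer(Nh), eps_rel = eps_rel),
            class = "mac_descriptor_config")
}

as_volume_data <- function(I) {
  if (inherits(I, "mac_volume")) I$data else as_array3d(I)
}

grid_of <- function(I) {
  if (inherits(I, c("mac_volume", "mac_label", "mac_field")))
    list(spacing = I$spacing, origin = I$origin)
  else list(spacing = c(1, 1, 1), origin = c(0, 0, 0))
}

new_featmap <- function(data, channel_meta, grid, M = NA_integer_,
                        N = NA_integer_) {
  structure(list(data = data, channel_meta = channel_meta,
                 spacing = grid$spacing, origin = grid$origin,
                 M = M, N = N),
            class = "mac_featmap")
}

#' @export
print.mac_featmap <- function(x, ...) {
  cat(sprintf("<mac_featmap> %s voxels x %d channels (%s)\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              paste(unique(x$channel_meta$descriptor), collapse = ", ")))
  invisible(x)
}

#' Patch sum-of-squared-differences map
#'
#' Value at voxel p is the mean squared difference between the `R1^3`
#' patch centred at `p + offset_i` and the one at `p + offset_j`
#' (the patch SSD normalized by the patch voxel count). Computed by
#' shifting the image by each offset, squaring the difference, and box
#' filtering with the uniform `R1^3` averaging kernel; borders use edge
#' replication.
#'
#' @param I a [mac_volume()] or 3D array.
#' @param offset_i,offset_j integer length-3 patch-centre offsets (voxels).
#' @param R1 odd patch edge length in voxels.
#' @return 3D array of SSD values (same grid as `I`).
#' @export
patch_ssd_map <- function(I, offset_i, offset_j, R1) {
  a <- as_volume_data(I)
  if (R1 %% 2L != 1L) stop("R1 must be odd")
  d2 <- (shift3d(a, as.integer(offset_i)) -
           shift3d(a, as.integer(offset_j)))^2
  box_mean3d(d2, as.integer(R1))
}

# Floor a denominator map: values below eps_rel times its global mean
# (with an absolute floor of 1e-12) are clamped, so flat regions where
# the descriptor is 0/0 come out as exp(0) = 1.
floor_denominator <- function(denom, eps_rel) {
  floor_val <- max(eps_rel * mean(denom), 1e-12)
  pmax(denom, floor_val)
}

# Fixed neighbour order for MIND channels: +x, -x, +y, -y, +z, -z.
mind_neighbour_offsets <- function(L) {
  rbind(c(L, 0, 0), c(-L, 0, 0), c(0, L, 0), c(0, -L, 0),
        c(0, 0, L), c(0, 0, -L))
}

#' MIND descriptor (6-channel modality-independent neighbourhood descriptor)
#'
#' Channel n at voxel x is `exp(-D_n(x) / V(x))` where `D_n` is the mean
#' squared patch difference between the patch at x and the patch at its
#' n-th 6-neighbour at distance `L`, and `V` is the mean of the six `D_n`
#' (a local variance estimate), floored on flat regions so that constant
#' images yield channel value 1. Channels follow the fixed neighbour order
#' +x, -x, +y, -y, +z, -z. MIND is exactly invariant under positive affine
#' intensity maps `I -> a I + b`.
#'
#' @param I a [mac_volume()] or 3D array.
#' @param L neighbour distance in voxels.
#' @param R1 odd patch edge length.
#' @param eps_rel relative floor for the variance denominator.
#' @return a 6-channel feature map (`mac_featmap`).
#' @export
mind_descriptor <- function(I, L = 2L, R1 = 5L, eps_rel = 1e-6) {
  a <- as_volume_data(I)
  min_size <- L + (R1 - 1L) %/% 2L + 1L
  if (any(dim(a) < min_size))
    stop(sprintf("image smaller than the MIND footprint (min %d per axis)",
                 min_size))
  offs <- mind_neighbour_offsets(as.integer(L))
  dmaps <- lapply(seq_len(6), function(n)
    patch_ssd_map(a, c(0L, 0L, 0L), offs[n, ], R1))
  V <- Reduce(`+`, dmaps) / 6
  V <- floor_denominator(V, eps_rel)
  out <- array(0, c(dim(a), 6L))
  for (n in seq_len(6)) out[, , , n] <- exp(-dmaps[[n]] / V)
  meta <- data.frame(
    channel = seq_len(6), descriptor = "mind", scale = 1L,
    offset = apply(offs, 1, paste, collapse = ","),
    stringsAsFactors = FALSE)
  new_featmap(out, meta, grid_of(I), M = 6L, N = 1L)
}

#' Self-similarity context feature map (18 channels per scale)
#'
#' One channel per patch connection of the layout: for connection
#' (P_i, P_j) at voxel p the value is
#' `exp(-e_P * SSD_ij(p) / sum_pairs SSD(p))`, i.e. the exponential of the
#' connection's SSD normalized by the mean SSD over all 18 connections
#' (denominator floored on flat regions). Channels follow the layout's
#' frozen pair order.
#'
#' @param I a [mac_volume()] or 3D array.
#' @param layout a [build_connection_layout()] result.
#' @param R1 odd patch edge length.
#' @param eps_rel relative floor for the normalizing denominator.
#' @return an 18-channel `mac_featmap`.
#' @export
ssc_feature_map <- function(I, layout, R1 = 5L, eps_rel = 1e-6) {
  a <- as_volume_data(I)
  np <- nrow(layout$pairs)
  ssd <- vector("list", np)
  for (q in seq_len(np)) {
    oi <- layout$offsets[layout$pairs[q, 1], ]
    oj <- layout$offsets[layout$pairs[q, 2], ]
    ssd[[q]] <- patch_ssd_map(a, oi, oj, R1)
  }
  mean_ssd <- Reduce(`+`, ssd) / np
  mean_ssd <- floor_denominator(mean_ssd, eps_rel)
  out <- array(0, c(dim(a), np))
  for (q in seq_len(np)) out[, , , q] <- exp(-ssd[[q]] / mean_ssd)
  meta <- data.frame(
    channel = seq_len(np), descriptor = "ssc", scale = layout$scale,
    pair_i = apply(layout$offsets[layout$pairs[, 1], , drop = FALSE], 1,
                   paste, collapse = ","),
    pair_j = apply(layout$offsets[layout$pairs[, 2], , drop = FALSE], 1,
                   paste, collapse = ","),
    orientation = layout$orientation_class,
    stringsAsFactors = FALSE)
  new_featmap(out, meta, grid_of(I), M = np, N = 1L)
}

#' Multi-scale self-similarity context
#'
#' Channel-wise weighted sum over scales of the per-scale SSC maps;
#' scale k samples its 6-neighbourhood at distance `k * L`, and channels
#' are aligned across scales by connection identity, so the result keeps
#' M = 18 channels.
#'
#' @param I a [mac_volume()] or 3D array.
#' @param cfg a [descriptor_config()].
#' @return an M-channel `mac_featmap`.
#' @export
msssc <- function(I, cfg = descriptor_config()) {
  a <- as_volume_data(I)
  min_size <- cfg$K * cfg$L + (cfg$R1 - 1L) %/% 2L + 1L
  if (any(dim(a) < min_size))
    stop(sprintf(
      "image smaller than the msSSC footprint at K=%d (min %d per axis)",
      cfg$K, min_size))
  out <- NULL
  meta <- NULL
  for (k in seq_len(cfg$K)) {
    lay <- build_connection_layout(k, cfg$L)
    sk <- ssc_feature_map(a, lay, cfg$R1, cfg$eps_rel)
    if (is.null(out)) {
      out <- cfg$alphas[k] * sk$data
      meta <- sk$channel_meta
      meta$descriptor <- "msssc"
      meta$scale <- NULL
    } else {
      out <- out + cfg$alphas[k] * sk$data
    }
  }
  new_featmap(out, meta, grid_of(I), M = dim(out)[4], N = 1L)
}

#' Aggregate an msSSC map over 3D log-polar bins
#'
#' Output channel (m, n) at voxel p is the mean of msSSC channel m over
#' the voxel offsets of bin n centred at p (average pooling per bin,
#' realised as convolution with the bin's averaging kernel; edge
#' replication at borders). Channels are ordered bin-major, pair-minor:
#' channel index = (n - 1) * M + m. Empty bins yield zero-filled channels
#' (a warning is raised when the bin partition is built).
#'
#' @param mss an M-channel `mac_featmap` (msSSC or SSC).
#' @param bins a [build_bin_assignment()] result.
#' @return an (M x N)-channel `mac_featmap`.
#' @export
aggregate_macmind <- function(mss, bins) {
  a <- mss$data
  d <- dim(a)
  if (any(d[1:3] < bins$R2))
    stop(sprintf("feature map smaller than the aggregation patch R2=%d",
                 bins$R2))
  M <- d[4]; N <- bins$n_bins
  mm <- matrix(a, nrow = prod(d[1:3]), ncol = M)
  out <- .bin_average_cpp(mm, as.integer(d[1:3]), bins$kernels)
  meta <- data.frame(
    channel = seq_len(M * N),
    descriptor = "macmind",
    bin = rep(seq_len(N), each = M),
    pair = rep(seq_len(M), times = N),
    stringsAsFactors = FALSE)
  grid <- list(spacing = mss$spacing, origin = mss$origin)
  new_featmap(out, meta, grid, M = M, N = N)
}

#' macMIND feature map (cascaded msSSC + log-polar aggregation)
#'
#' The full cascaded descriptor: multi-scale self-similarity context
#' followed by average pooling over 3D log-polar bins, yielding an
#' M x N channel map (18 x 32 = 576 at defaults). Deterministic given the
#' image and configuration, and exactly invariant under positive affine
#' intensity maps.
#'
#' @param I a [mac_volume()] or 3D array.
#' @param cfg a [descriptor_config()].
#' @param bins optional pre-built [build_bin_assignment()]; defaults to
#'   the configuration's `R2`, `Na`, `Nr`, `Nh`.
#' @return an (M x N)-channel `mac_featmap`.
#' @export
macmind <- function(I, cfg = descriptor_config(), bins = NULL) {
  a <- as_volume_data(I)
  min_size <- cfg$K * cfg$L + (cfg$R1 - 1L) %/% 2L + (cfg$R2 - 1L) %/% 2L + 1L
  if (any(dim(a) < min_size))
    stop(sprintf(
      "image smaller than the macMIND footprint (min %d voxels per axis for K=%d, L=%d, R1=%d, R2=%d)",
      min_size, cfg$K, cfg$L, cfg$R1, cfg$R2))
  if (is.null(bins))
    bins <- suppressWarnings(
      build_bin_assignment(cfg$R2, cfg$Na, cfg$Nr, cfg$Nh))
  mss <- msssc(I, cfg)
  aggregate_macmind(mss, bins)
}

#' Extract a feature map by name
#'
#' Dispatcher used by the command line: `"macmind"`, `"mind"` or `"ssc"`.
#'
#' @param I a [mac_volume()] or 3D array.
#' @param cfg a [descriptor_config()].
#' @param descriptor one of `"macmind"`, `"mind"`, `"ssc"`, `"msssc"`.
#' @return a `mac_featmap`.
#' @export
extract_features <- function(I, cfg = descriptor_config(),
                             descriptor = c("macmind", "mind", "ssc",
                                            "msssc")) {
  descriptor <- match.arg(descriptor)
  switch(descriptor,
    macmind = macmind(I, cfg),
    mind = mind_descriptor(I, cfg$L, cfg$R1, cfg$eps_rel),
    ssc = ssc_feature_map(I, build_connection_layout(1L, cfg$L), cfg$R1,
                          cfg$eps_rel),
    msssc = msssc(I, cfg))
}

#' Write / read a feature map as 4D NIfTI plus a JSON sidecar
#'
#' The NIfTI carries the channels on the 4th axis; the sidecar
#' (`<path>.json`) carries the channel metadata and, when supplied, the
#' descriptor configuration.
#'
#' @param fm a `mac_featmap`.
#' @param path output NIfTI path.
#' @param cfg optional [descriptor_config()] echoed into the sidecar.
#' @export
write_featmap <- function(fm, path, cfg = NULL) {
  img <- nifti_from(fm$data, fm$spacing, fm$origin)
  RNifti::writeNifti(img, path, datatype = "float")
  sidecar <- list(M = fm$M, N = fm$N, channel_meta = fm$channel_meta)
  if (!is.null(cfg)) sidecar$config <- unclass(cfg)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
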
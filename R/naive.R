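# Naive per-voxel reference implementations of the descriptor stages.
# These evaluate the defining patch sums directly with explicit index
# clamping and no convolution tricks; they are intentionally slow and
# exist so the fast shift-and-convolve path can be checked against an
# independent computation on small volumes.

clamp_idx <- function(i, n) pmin.int(pmax.int(i, 1L), n)

# Patch offsets of an odd w^3 patch as an n x 3 integer matrix.
patch_offsets <- function(w) {
  r <- (w - 1L) %/% 2L
  as.matrix(expand.grid(x = (-r):r, y = (-r):r, z = (-r):r))
}

# Mean squared difference between the patches at (p + oi) and (p + oj),
# p given as a 1-based length-3 index. Every coordinate is clamped to the
# grid independently, matching edge-replication semantics.
.naive_patch_ssd_at <- function(a, p, oi, oj, tmat) {
  d <- dim(a)
  qi <- sweep(tmat, 2, p + oi, `+`)
  qj <- sweep(tmat, 2, p + oj, `+`)
  ii <- cbind(clamp_idx(qi[, 1], d[1]), clamp_idx(qi[, 2], d[2]),
              clamp_idx(qi[, 3], d[3]))
  jj <- cbind(clamp_idx(qj[, 1], d[1]), clamp_idx(qj[, 2], d[2]),
              clamp_idx(qj[, 3], d[3]))
  mean((a[ii] - a[jj])^2)
}

# The fast path applies the offset shifts first (clamped) and box-filters
# the squared difference afterwards (clamped again), so the reference
# must clamp in the same two stages at the border: patch voxel position
# q = clamp(p + t), then compare a[clamp(q + oi)] with a[clamp(q + oj)].
.naive_patch_ssd_two_stage <- function(a, p, oi, oj, tmat) {
  d <- dim(a)
  q <- sweep(tmat, 2, p, `+`)
  q <- cbind(clamp_idx(q[, 1], d[1]), clamp_idx(q[, 2], d[2]),
             clamp_idx(q[, 3], d[3]))
  qi <- sweep(q, 2, oi, `+`)
  qj <- sweep(q, 2, oj, `+`)
  ii <- cbind(clamp_idx(qi[, 1], d[1]), clamp_idx(qi[, 2], d[2]),
              clamp_idx(qi[, 3], d[3]))
  jj <- cbind(clamp_idx(qj[, 1], d[1]), clamp_idx(qj[, 2], d[2]),
              clamp_idx(qj[, 3], d[3]))
  mean((a[ii] - a[jj])^2)
}

#' Naive patch SSD map (reference implementation)
#'
#' Direct double loop over voxels and patch offsets; see
#' [patch_ssd_map()] for the definition.
#'
#' @inheritParams patch_ssd_map
#' @return 3D array of SSD values.
#' @export
patch_ssd_map_naive <- function(I, offset_i, offset_j, R1) {
  a <- as_volume_data(I)
  if (R1 %% 2L != 1L) stop("R1 must be odd")
  d <- dim(a)
  tmat <- patch_offsets(R1)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    out[i, j, k] <- .naive_patch_ssd_two_stage(
      a, c(i, j, k), as.integer(offset_i), as.integer(offset_j), tmat)
  out
}

#' Naive MIND descriptor (reference implementation)
#' @inheritParams mind_descriptor
#' @return 6-channel `mac_featmap`.
#' @export
mind_descriptor_naive <- function(I, L = 2L, R1 = 5L, eps_rel = 1e-6) {
  a <- as_volume_data(I)
  offs <- mind_neighbour_offsets(as.integer(L))
  dmaps <- lapply(seq_len(6), function(n)
    patch_ssd_map_naive(a, c(0L, 0L, 0L), offs[n, ], R1))
  V <- Reduce(`+`, dmaps) / 6
  floor_val <- max(eps_rel * mean(V), 1e-12)
  out <- array(0, c(dim(a), 6L))
  for (n in seq_len(6)) out[, , , n] <- exp(-dmaps[[n]] / pmax(V, floor_val))
  meta <- data.frame(channel = seq_len(6), descriptor = "mind", scale = 1L,
                     offset = apply(offs, 1, paste, collapse = ","),
                     stringsAsFactors = FALSE)
  new_featmap(out, meta, grid_of(I), M = 6L, N = 1L)
}

#' Naive self-similarity context (reference implementation)
#' @inheritParams ssc_feature_map
#' @return 18-channel `mac_featmap`.
#' @export
ssc_feature_map_naive <- function(I, layout, R1 = 5L, eps_rel = 1e-6) {
  a <- as_volume_data(I)
  np <- nrow(layout$pairs)
  ssd <- lapply(seq_len(np), function(q)
    patch_ssd_map_naive(a, layout$offsets[layout$pairs[q, 1], ],
                        layout$offsets[layout$pairs[q, 2], ], R1))
  mean_ssd <- Reduce(`+`, ssd) / np
  floor_val <- max(eps_rel * mean(mean_ssd), 1e-12)
  mean_ssd <- pmax(mean_ssd, floor_val)
  out <- array(0, c(dim(a), np))
  for (q in seq_len(np)) out[, , , q] <- exp(-ssd[[q]] / mean_ssd)
  new_featmap(out, data.frame(channel = seq_len(np), descriptor = "ssc",
                              stringsAsFactors = FALSE),
              grid_of(I), M = np, N = 1L)
}

#' Naive msSSC (reference implementation)
#' @inheritParams msssc
#' @return M-channel `mac_featmap`.
#' @export
msssc_naive <- function(I, cfg = descriptor_config()) {
  out <- NULL
  for (k in seq_len(cfg$K)) {
    lay <- build_connection_layout(k, cfg$L)
    sk <- ssc_feature_map_naive(I, lay, cfg$R1, cfg$eps_rel)
    out <- if (is.null(out)) cfg$alphas[k] * sk$data
           else out + cfg$alphas[k] * sk$data
  }
  new_featmap(out, data.frame(channel = seq_len(dim(out)[4]),
                              descriptor = "msssc",
                              stringsAsFactors = FALSE),
              grid_of(I), M = dim(out)[4], N = 1L)
}

#' Naive log-polar bin aggregation (reference implementation)
#'
#' Direct per-voxel bin averaging with clamped indices.
#'
#' @inheritParams aggregate_macmind
#' @return (M x N)-channel `mac_featmap`.
#' @export
aggregate_macmind_naive <- function(mss, bins) {
  a <- mss$data
  d <- dim(a)
  M <- d[4]; N <- bins$n_bins
  out <- array(0, c(d[1:3], M * N))
  for (n in seq_len(N)) {
    offs <- bins$kernels[[n]]
    cnt <- nrow(offs)
    if (cnt == 0L) next
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      q <- cbind(clamp_idx(i + offs[, 1], d[1]),
                 clamp_idx(j + offs[, 2], d[2]),
                 clamp_idx(k + offs[, 3], d[3]))
      for (m in seq_len(M)) {
        out[i, j, k, (n - 1L) * M + m] <- mean(a[cbind(q, m)])
      }
    }
  }
  new_featmap(out, data.frame(channel = seq_len(M * N),
                              descriptor = "macmind",
                              stringsAsFactors = FALSE),
              list(spacing = mss$spacing, origin = mss$origin),
              M = M, N = N)
}

#' Naive end-to-end macMIND (reference implementation)
#'
#' Composition of the naive msSSC and naive bin aggregation.
#'
#' @inheritParams macmind
#' @return (M x N)-channel `mac_featmap`.
#' @export
macmind_naive <- function(I, cfg = descriptor_config(), bins = NULL) {
  if (is.null(bins))
    bins <- suppressWarnings(
      build_bin_assignment(cfg$R2, cfg$Na, cfg$Nr, cfg$Nh))
  aggregate_macmind_naive(msssc_naive(I, cfg), bins)
}
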
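# Patch-pair sampling patterns for the self-similarity context, and the
# 3D log-polar bin partition used by the cascaded aggregation stage.

#' Build the patch-connection layout for one sampling scale
#'
#' The layout places a central patch and its 6 axis neighbours at distance
#' `scale * L` voxels, and connects every non-collinear patch pair: 18
#' undirected connections falling into 9 undirected orientation classes
#' (3 axis classes from the centre-to-neighbour connections, 6 diagonal
#' classes from the neighbour-to-neighbour ones). The 3 collinear
#' opposite-neighbour pairs are excluded. The classic MIND pattern is the
#' 6-connection / 3-orientation sub-layout of centre-to-neighbour pairs.
#'
#' Pairs are ordered lexicographically by (orientation class, offset), a
#' frozen ordering that fixes descriptor channel order.
#'
#' @param scale positive integer sampling scale k.
#' @param L base patch distance in voxels (>= 1).
#' @return object of class `mac_layout`: list with `scale`, `L`, `offsets`
#'   (7 x 3 integer matrix, centre first), `pairs` (18 x 2 indices into
#'   `offsets`), `orientation_class` (length-18 integer), `e_p` (= 18),
#'   and `mind_pairs` (logical marking the 6 centre-to-neighbour pairs).
#' @examples
#' lay <- build_connection_layout(1, 2)
#' lay$e_p                       # 18
#' length(unique(lay$orientation_class))  # 9
#' @export
build_connection_layout <- function(scale, L) {
  scale <- as.integer(scale); L <- as.integer(L)
  if (scale < 1L || L < 1L) stop("scale and L must be >= 1")
  d <- scale * L
  offsets <- rbind(c(0, 0, 0),
                   c(d, 0, 0), c(-d, 0, 0),
                   c(0, d, 0), c(0, -d, 0),
                   c(0, 0, d), c(0, 0, -d))
  storage.mode(offsets) <- "integer"
  n <- nrow(offsets)
  pairs <- list(); dirs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      v <- offsets[j, ] - offsets[i, ]
      if (all(v == 0)) next
      # collinear opposite neighbours: difference parallel to an axis with
      # both endpoints off-centre
      if (i > 1L && sum(v != 0) == 1L) next
      pairs[[length(pairs) + 1L]] <- c(i, j)
      dirs[[length(dirs) + 1L]] <- v
    }
  }
  pairs <- do.call(rbind, pairs)
  # undirected orientation class: direction vector normalized to a
  # canonical sign (first nonzero component positive), then to unit steps
  canon <- t(vapply(dirs, function(v) {
    s <- sign(v[which(v != 0)[1]])
    v <- v * s
    v %/% max(abs(v))
  }, numeric(3)))
  keys <- apply(canon, 1, paste, collapse = ",")
  classes <- sort(unique(keys))
  orientation_class <- match(keys, classes)
  mind_pairs <- pairs[, 1] == 1L
  ord <- order(orientation_class, pairs[, 1], pairs[, 2])
  structure(list(scale = scale, L = L, offsets = offsets,
                 pairs = pairs[ord, , drop = FALSE],
                 orientation_class = orientation_class[ord],
                 orientation_keys = classes,
                 e_p = nrow(pairs),
                 mind_pairs = mind_pairs[ord]),
            class = "mac_layout")
}

#' @export
print.mac_layout <- function(x, ...) {
  cat(sprintf(
    "<mac_layout> scale %d, distance %d: %d connections, %d orientations\n",
    x$scale, x$scale * x$L, x$e_p, length(unique(x$orientation_class))))
  invisible(x)
}

#' Partition an aggregation patch into 3D log-polar bins
#'
#' Each voxel offset of the `R2^3` patch is mapped to a bin by cylindrical
#' log-polar coordinates: azimuth in the x-y plane into `Na` equal sectors
#' (starting at +x, counter-clockwise; a boundary angle belongs to the
#' sector it starts), xy-radius into `Nr` log-spaced shells over
#' `(0, R2/2]` (consecutive shell outer radii in ratio 2, innermost shell
#' closed at 0 so the r = 0 column is assigned to it), and the z offset
#' into `Nh` equal slabs. Offsets whose xy-radius exceeds `R2/2` fall
#' outside the inscribed cylinder and stay unassigned. With `Nh = 1` and a
#' flat patch this reduces to the planar `Na x Nr` pattern (e.g. 8 angle
#' and 2 radial intervals giving 16 bins).
#'
#' Bins are ordered (height, radius, angle), slowest to fastest; this
#' frozen ordering fixes the aggregated channel order.
#'
#' @param R2 odd aggregation patch edge length in voxels.
#' @param Na,Nr,Nh number of angular / radial / height intervals (>= 1).
#' @param flat if `TRUE`, use a flat `R2 x R2 x 1` patch (2D illustration
#'   mode); requires `Nh = 1`.
#' @return object of class `mac_bins`: list with `R2`, `n_bins`,
#'   `offsets` (all patch offsets, n x 3), `bin` (bin index per offset, NA
#'   if unassigned), `counts` (voxels per bin) and `kernels` (per bin, the
#'   offset list of its averaging kernel).
#' @export
build_bin_assignment <- function(R2, Na = 8L, Nr = 2L, Nh = 2L, flat = FALSE) {
  if (R2 %% 2L != 1L || R2 < 1L) stop("R2 must be odd and positive")
  if (any(c(Na, Nr, Nh) < 1L)) stop("Na, Nr, Nh must be >= 1")
  if (flat && Nh != 1L) stop("flat mode requires Nh = 1")
  r <- (R2 - 1L) %/% 2L
  zs <- if (flat) 0L else (-r):r
  offsets <- as.matrix(expand.grid(x = (-r):r, y = (-r):r, z = zs))
  storage.mode(offsets) <- "integer"
  rmax <- R2 / 2
  n_bins <- as.integer(Na * Nr * Nh)
  rho <- sqrt(offsets[, 1]^2 + offsets[, 2]^2)
  bin <- rep(NA_integer_, nrow(offsets))
  inside <- rho <= rmax
  # azimuth sector (0-based), +x start, counter-clockwise; rho = 0 column
  # goes to the first sector by convention
  theta <- atan2(offsets[, 2], offsets[, 1]) %% (2 * pi)
  ang <- pmin(floor(theta / (2 * pi / Na)), Na - 1L)
  ang[rho == 0] <- 0L
  # log-spaced shells: outer radii rmax / 2^(Nr - s), s = 1..Nr; shell 1
  # closed at zero
  shell_outer <- rmax / 2^((Nr - 1):0)
  rad <- vapply(rho, function(x) {
    which(x <= shell_outer + 1e-12)[1]
  }, integer(1)) - 1L
  # equal z slabs over [-rmax, rmax]
  hgt <- if (flat) rep(0L, nrow(offsets)) else
    pmin(floor((offsets[, 3] + rmax) / (2 * rmax / Nh)), Nh - 1L)
  idx0 <- hgt * (Nr * Na) + rad * Na + ang   # (height, radius, angle) order
  bin[inside] <- idx0[inside] + 1L
  counts <- tabulate(bin, nbins = n_bins)
  kernels <- lapply(seq_len(n_bins), function(b) {
    offsets[!is.na(bin) & bin == b, , drop = FALSE]
  })
  empty <- which(counts == 0L)
  if (length(empty) > 0L)
    warning(sprintf(
      "%d of %d log-polar bins are empty at R2=%d (Na=%d, Nr=%d, Nh=%d); %s",
      length(empty), n_bins, R2, Na, Nr, Nh,
      "their aggregated channels will be zero-filled"))
  structure(list(R2 = as.integer(R2), Na = as.integer(Na),
                 Nr = as.integer(Nr), Nh = as.integer(Nh),
                 flat = flat, n_bins = n_bins,
                 offsets = offsets, bin = bin, counts = counts,
                 kernels = kernels),
            class = "mac_bins")
}

#' @export
print.mac_bins <- function(x, ...) {
  cat(sprintf(
    "<mac_bins> R2=%d, %d bins (Na=%d Nr=%d Nh=%d), %d/%d offsets assigned, %d empty bins\n",
    x$R2, x$n_bins, x$Na, x$Nr, x$Nh,
    sum(!is.na(x$bin)), nrow(x$offsets), sum(x$counts == 0L)))
  invisible(x)
}
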
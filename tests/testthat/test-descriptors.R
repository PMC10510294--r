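# Descriptor stages against their naive per-voxel oracles, plus the
# structural invariances (positive-affine intensity invariance, value
# range, determinism).

test_that("patch SSD map matches the brute-force patch loop", {
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 1   # single bright voxel
  fast <- patch_ssd_map(a, c(0, 0, 0), c(2, 0, 0), 3)
  slow <- patch_ssd_map_naive(a, c(0, 0, 0), c(2, 0, 0), 3)
  expect_equal(fast, slow, tolerance = 1e-12)

  set.seed(21)
  r <- array(runif(9^3), c(9, 9, 9))
  expect_equal(patch_ssd_map(r, c(1, -1, 0), c(0, 2, 1), 3),
               patch_ssd_map_naive(r, c(1, -1, 0), c(0, 2, 1), 3),
               tolerance = 1e-12)
})

test_that("patch SSD is quadratic in intensity scale and zero on flats", {
  expect_equal(patch_ssd_map(array(3.7, c(7, 7, 7)), c(0, 0, 0),
                             c(1, 0, 0), 3),
               array(0, c(7, 7, 7)))
  set.seed(22)
  a <- array(runif(7^3), c(7, 7, 7))
  s1 <- patch_ssd_map(a, c(0, 0, 0), c(1, 1, 0), 3)
  s2 <- patch_ssd_map(2.5 * a, c(0, 0, 0), c(1, 1, 0), 3)
  expect_equal(s2, 2.5^2 * s1, tolerance = 1e-12)
})

test_that("MIND equals its naive oracle and is affine invariant", {
  set.seed(23)
  a <- array(runif(7^3), c(7, 7, 7))
  fast <- mind_descriptor(a, L = 1, R1 = 3)
  slow <- mind_descriptor_naive(a, L = 1, R1 = 3)
  expect_lt(max(abs(fast$data - slow$data)), 1e-6)
  expect_identical(mind_descriptor(2 * a + 5, L = 1, R1 = 3)$data,
                   fast$data)
  # constant image: all six channels are exactly 1 under the floor rule
  flat <- mind_descriptor(array(4, c(7, 7, 7)), L = 1, R1 = 3)
  expect_equal(flat$data, array(1, c(7, 7, 7, 6)))
  expect_true(all(fast$data > 0 & fast$data <= 1))
})

test_that("SSC equals its naive oracle with the 18-channel normalization", {
  set.seed(24)
  a <- array(runif(9^3), c(9, 9, 9))
  lay <- build_connection_layout(1, 2)
  fast <- ssc_feature_map(a, lay, R1 = 3)
  slow <- ssc_feature_map_naive(a, lay, R1 = 3)
  expect_lt(max(abs(fast$data - slow$data)), 1e-6)
  # per voxel, sum of -log(channel) equals the 18 connections when no
  # flooring is active
  nl <- -log(pmax(fast$data, 1e-300))
  expect_equal(apply(nl, 1:3, sum), array(18, c(9, 9, 9)),
               tolerance = 1e-8)
  flat <- ssc_feature_map(array(2, c(9, 9, 9)), lay, R1 = 3)
  expect_equal(flat$data, array(1, c(9, 9, 9, 18)))
})

test_that("msSSC is the stated weighted combination of per-scale SSC", {
  set.seed(25)
  a <- array(runif(12^3), c(12, 12, 12))
  cfg1 <- descriptor_config(K = 1, alphas = 1, L = 1, R1 = 3)
  expect_equal(msssc(a, cfg1)$data,
               ssc_feature_map(a, build_connection_layout(1, 1),
                               R1 = 3)$data)
  cfg2 <- descriptor_config(K = 2, alphas = c(0.7, 0.3), L = 1, R1 = 3)
  s1 <- ssc_feature_map(a, build_connection_layout(1, 1), R1 = 3)$data
  s2 <- ssc_feature_map(a, build_connection_layout(2, 1), R1 = 3)$data
  expect_equal(msssc(a, cfg2)$data, 0.7 * s1 + 0.3 * s2,
               tolerance = 1e-12)
  out <- msssc(a, cfg2)$data
  expect_true(all(out > 0 & out <= 1))
})

test_that("bin aggregation averages constants and matches the naive oracle", {
  bins <- suppressWarnings(build_bin_assignment(5, 8, 2, 2))
  dims <- c(11, 11, 11)
  M <- 3
  vals <- c(0.2, 0.5, 0.9)
  uni <- array(rep(vals, each = prod(dims)), c(dims, M))
  fm <- macmind:::new_featmap(uni, data.frame(channel = 1:M),
                              list(spacing = c(1, 1, 1),
                                   origin = c(0, 0, 0)))
  agg <- aggregate_macmind(fm, bins)
  expect_equal(dim(agg$data)[4], M * bins$n_bins)
  for (n in seq_len(bins$n_bins)) {
    for (m in seq_len(M)) {
      expected <- if (bins$counts[n] == 0) 0 else vals[m]
      expect_equal(max(abs(agg$data[, , , (n - 1) * M + m] - expected)), 0)
    }
  }
  set.seed(26)
  rnd <- array(runif(prod(dims) * M), c(dims, M))
  fm2 <- macmind:::new_featmap(rnd, data.frame(channel = 1:M),
                               list(spacing = c(1, 1, 1),
                                    origin = c(0, 0, 0)))
  expect_lt(max(abs(aggregate_macmind(fm2, bins)$data -
                      aggregate_macmind_naive(fm2, bins)$data)), 1e-6)
})

test_that("macMIND is affine invariant, translation covariant, in (0,1]", {
  set.seed(27)
  a <- array(runif(14 * 14 * 12), c(14, 14, 12))
  cfg <- descriptor_config(L = 1, R1 = 3, R2 = 3, K = 2,
                           alphas = c(0.7, 0.3), Na = 4, Nr = 1, Nh = 2)
  f <- macmind(a, cfg)
  expect_lt(max(abs(macmind(0.8 * a + 2, cfg)$data - f$data)), 1e-12)
  expect_equal(dim(f$data)[4], f$M * f$N)
  nonzero <- f$data[f$data != 0]
  expect_true(all(nonzero > 0 & nonzero <= 1))
  # determinism: bit-identical on recomputation
  expect_identical(macmind(a, cfg)$data, f$data)

  # translating the image translates the feature map wherever the
  # descriptor support (K*L + patch radii = 4 voxels here) stays clear
  # of both the border and the shifted-in replicated slab
  sh <- macmind:::shift3d(a, c(2, 0, 0))
  fs <- macmind(sh, cfg)
  ix <- 5:8
  expect_equal(fs$data[ix, , , ], f$data[ix + 2, , , ], tolerance = 1e-12)
})

test_that("macMIND end-to-end equals the composed naive oracle", {
  set.seed(28)
  a <- array(runif(12^3), c(12, 12, 12))
  cfg <- descriptor_config(L = 1, R1 = 3, R2 = 5, K = 2,
                           alphas = c(0.7, 0.3), Na = 8, Nr = 2, Nh = 2)
  expect_lt(max(abs(macmind(a, cfg)$data - macmind_naive(a, cfg)$data)),
            1e-5)
})

test_that("footprint and configuration errors are informative", {
  expect_error(macmind(array(0, c(6, 6, 6))), "min")
  expect_error(descriptor_config(K = 2, alphas = 1), "length")
  expect_error(descriptor_config(R1 = 4), "odd")
  expect_error(msssc(array(0, c(4, 4, 4)), descriptor_config()),
               "footprint")
})
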
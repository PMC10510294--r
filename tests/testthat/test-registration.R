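test_that("warping through the zero field is the exact identity", {
  v <- rand_vol(c(8, 8, 8), seed = 41)
  zf <- zero_field(c(8, 8, 8))
  expect_identical(warp(v, zf)$data, v$data)
  l <- mac_label(array(sample(0:2, 512, replace = TRUE), c(8, 8, 8)))
  expect_identical(warp(l, zf, "nearest")$data, l$data)
})

test_that("constant integer fields shift the image on the interior", {
  v <- rand_vol(c(8, 8, 8), seed = 42)
  w <- warp(v, const_field(c(8, 8, 8), c(1, 0, 0)))
  expect_equal(w$data[1:7, , ], v$data[2:8, , ])
  w2 <- warp(v, const_field(c(8, 8, 8), c(0, -2, 0)))
  expect_equal(w2$data[, 3:8, ], v$data[, 1:6, ])
})

test_that("trilinear warping is exact on linear images at half-voxel", {
  ramp <- mac_volume(array(rep(0:7, times = 64), c(8, 8, 8)))
  w <- warp(ramp, const_field(c(8, 8, 8), c(0.5, 0, 0)))
  expect_equal(w$data[1:7, , ],
               array(rep(0:6 + 0.5, times = 64), c(7, 8, 8)))
})

test_that("Jacobian report counts folding correctly", {
  zr <- jacobian_report(zero_field(c(8, 8, 8)))
  expect_equal(zr$folding_count, 0L)
  expect_equal(zr$min_det, 1)
  expect_equal(zr$total_voxels, 6^3)
  expect_equal(zr$folding_per_ten_thousand, 0)

  # any constant displacement has det == 1 everywhere
  set.seed(43)
  for (i in 1:5) {
    cf <- const_field(c(6, 6, 6), rnorm(3, 0, 2))
    expect_equal(jacobian_report(cf)$folding_count, 0L)
  }

  # a reflection along x (phi_x = -2x + c on a strip) folds
  refl <- array(0, c(10, 10, 10, 3))
  refl[, , , 1] <- array(rep(-2 * (0:9) + 9, times = 100), c(10, 10, 10))
  rr <- jacobian_report(mac_field(refl))
  expect_gt(rr$folding_count, 0)
  expect_lt(rr$min_det, 0)

  # smooth small-amplitude synthetic field stays fold-free
  sm <- generate_deformation(phantom_config(size = c(24, 24, 24),
                                            seed = 44, amplitude = 1,
                                            sigma = 4))
  expect_equal(jacobian_report(sm)$folding_count, 0L)
  expect_error(jacobian_report(zero_field(c(2, 4, 4))), "at least 3")
})

test_that("self-registration stays at the identity", {
  ph <- small_phantom()
  cfg <- registration_config(levels = 2L, iterations = 4L)
  res <- register(ph$vol_a, ph$vol_a, cfg)
  tr <- res$trace
  expect_lte(tr$e_sim[nrow(tr)], tr$e_sim[1] + 1e-12)
  m <- sqrt(res$field$data[, , , 1]^2 + res$field$data[, , , 2]^2 +
              res$field$data[, , , 3]^2)
  expect_lt(mean(m), 0.1)
})

test_that("accepted loss trace is non-increasing within every level", {
  ph <- small_phantom()
  cfg <- registration_config(levels = c(2L, 1L), iterations = c(4L, 3L),
                             descriptor = descriptor_config(Na = 4L,
                                                            Nr = 1L))
  res <- register(ph$vol_a, ph$vol_b, cfg,
                  fixed_label = ph$label_organ_a,
                  moving_label = ph$label_organ_b)
  for (lv in unique(res$trace$level)) {
    tot <- res$trace$e_total[res$trace$level == lv]
    expect_true(all(diff(tot) <= 1e-12))
  }
  expect_equal(dim(res$field$data), c(dim(ph$vol_a$data), 3L))
  # final total never exceeds the starting total of its level
  first <- res$trace$e_total[!duplicated(res$trace$level)]
  last <- rev(res$trace$e_total[!duplicated(res$trace$level,
                                            fromLast = TRUE)])
  expect_true(all(rev(first) - last >= -1e-12))
})

test_that("registration rejects mismatched grids", {
  a <- rand_vol(c(16, 16, 16), seed = 45)
  b <- rand_vol(c(16, 16, 18), seed = 46)
  expect_error(register(a, b), "grid")
  expect_error(warp(a$data, zero_field(c(8, 8, 8))), "grid")
})
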
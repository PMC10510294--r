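test_that("mutual information identities under shared binning", {
  v <- rand_vol(c(16, 16, 16), seed = 51)
  expect_equal(mutual_information(v, v), shannon_entropy(v),
               tolerance = 1e-12)
  # monotone affine rescaling leaves the histogram, hence MI, unchanged
  v2 <- mac_volume(3.2 * v$data + 7)
  expect_equal(mutual_information(v, v2), mutual_information(v, v),
               tolerance = 1e-12)
  expect_warning(mi0 <- mutual_information(mac_volume(array(1, c(4, 4, 4))),
                                           v <- rand_vol(c(4, 4, 4))),
                 "constant")
  expect_equal(mi0, 0)
})

test_that("independent noise volumes carry almost no mutual information", {
  for (s in 1:3) {
    a <- rand_vol(c(32, 32, 32), seed = 100 + s)
    b <- rand_vol(c(32, 32, 32), seed = 200 + s)
    expect_lt(mutual_information(a, b, bins = 32), 0.05)
  }
})

test_that("global SSIM identities and direct formula", {
  v <- rand_vol(c(16, 16, 16), seed = 52)
  expect_equal(ssim(v, v), 1)
  # anti-correlated pair scores below the identity
  half <- mac_volume(array(rep(c(0, 1), each = 8 * 16 * 16 / 2),
                           c(16, 16, 16)))
  inv <- mac_volume(1 - half$data)
  expect_lt(ssim(half, inv), ssim(half, half))
  # direct evaluation of the product form
  w <- rand_vol(c(16, 16, 16), seed = 53)
  x <- v$data; y <- w$data
  n01 <- function(z) (z - min(z)) / (max(z) - min(z))
  x <- n01(x); y <- n01(y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  c1 <- 0.01^2; c2 <- 0.03^2
  direct <- (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  expect_equal(ssim(v, w), direct, tolerance = 1e-12)
  literal <- ((2 * mx * my + c1) + (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  expect_equal(ssim(v, w, paper_literal = TRUE), literal,
               tolerance = 1e-12)
  # the literal sum-form numerator does not attain 1 at identity, which
  # is why the product form is the default
  expect_false(isTRUE(all.equal(ssim(v, v, paper_literal = TRUE), 1)))
})

test_that("overlap metrics on constructed masks", {
  cube <- array(0L, c(12, 12, 12)); cube[2:5, 2:5, 2:5] <- 1L
  expect_equal(dsc(cube, cube), 100)
  far <- array(0L, c(12, 12, 12)); far[8:11, 8:11, 8:11] <- 1L
  expect_equal(dsc(cube, far), 0)
  expect_equal(voe(cube, cube), 0)
  expect_equal(voe(cube, far), 100)
  # |A| = |B| = 8, |A n B| = 4 -> DSC 50
  a <- array(0L, c(6, 6, 6)); a[1:2, 1:2, 1:2] <- 1L
  b <- array(0L, c(6, 6, 6)); b[1:2, 1:2, 2:3] <- 1L
  expect_equal(dsc(a, b), 50)
  expect_warning(d0 <- dsc(array(0L, c(3, 3, 3)), array(0L, c(3, 3, 3))),
                 "empty")
  expect_equal(d0, 100)
  expect_error(dsc(a, b, label_id = 7, strict = TRUE), "absent")
})

test_that("RVDabs follows the volume-ratio definition", {
  a <- array(0L, c(8, 8, 8)); a[1:2, 1:2, 1:2] <- 1L      # 8 voxels
  expect_equal(rvd_abs(a, a), 0)
  b <- array(0L, c(8, 8, 8)); b[1:4, 1:2, 1:2] <- 1L      # 16 voxels
  expect_equal(rvd_abs(b, a), 100)
  s12 <- array(0L, c(8, 8, 8)); s12[1:3, 1:2, 1:2] <- 1L  # 12 voxels
  s10 <- array(0L, c(8, 8, 8)); s10[1:5, 1:2, 1:1] <- 1L  # 10 voxels
  expect_equal(rvd_abs(s12, s10), 20)
  expect_error(rvd_abs(a, array(0L, c(8, 8, 8))), "empty")
})

test_that("Jaccard-Dice identity links DSC and VOE on random masks", {
  set.seed(54)
  for (i in 1:100) {
    a <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
    b <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
    if (sum(a) + sum(b) == 0 || sum(a | b) == 0) next
    d <- suppressWarnings(dsc(a, b)); v <- voe(a, b)
    expect_equal(d, 2 * (100 - v) / (200 - v) * 100, tolerance = 1e-10)
  }
})

test_that("Hd95 of a shifted cube and symmetry", {
  cube <- array(0L, c(14, 14, 14)); cube[2:5, 2:5, 2:5] <- 1L
  shifted <- array(0L, c(14, 14, 14)); shifted[5:8, 2:5, 2:5] <- 1L
  expect_equal(hd95(cube, cube, c(1, 1, 1)), 0)
  expect_equal(hd95(cube, shifted, c(1, 1, 1)), 3.0)
  expect_equal(hd95(shifted, cube, c(1, 1, 1)),
               hd95(cube, shifted, c(1, 1, 1)))
  # anisotropic spacing converts voxel offsets to mm
  zshift <- array(0L, c(14, 14, 14)); zshift[2:5, 2:5, 4:7] <- 1L
  expect_equal(hd95(cube, zshift, c(1, 1, 2.5)), 5.0)
  expect_error(hd95(cube, array(0L, c(14, 14, 14)), c(1, 1, 1)), "empty")
})

test_that("TRE maps landmarks through the field in mm", {
  zf <- zero_field(c(24, 24, 24))
  lmA <- mac_landmarks(data.frame(x = c(10, 5), y = c(10, 5),
                                  z = c(10, 5)), c("p", "q"))
  expect_equal(tre(lmA, lmA, zf)$tre_mm, c(0, 0))
  lmB <- mac_landmarks(data.frame(x = c(13, 5), y = c(14, 5),
                                  z = c(10, 5)), c("p", "q"))
  expect_equal(tre(lmB, lmA, zf)$tre_mm[1], 5)  # 3-4-5 triangle
  # a constant field moves the mapped point accordingly
  cf <- const_field(c(24, 24, 24), c(3, 4, 0))
  expect_equal(tre(lmB, lmA, cf)$tre_mm, c(0, 5))
  bad <- mac_landmarks(data.frame(x = 1, y = 1, z = 1), "r")
  expect_error(tre(bad, lmA, zf), "correspond")
  out <- mac_landmarks(data.frame(x = 500, y = 1, z = 1), c("p"))
  expect_error(tre(lmA[lmA$id == "p", ], out, zf), "outside")
})

test_that("metric panel bundles the full evaluation set", {
  ph <- small_phantom()
  zf <- zero_field(dim(ph$vol_a$data))
  panel <- metric_panel(ph$vol_a, ph$vol_b,
                        fixed_label = ph$label_organ_a,
                        warped_label = ph$label_organ_b,
                        target_lms = ph$landmarks_b,
                        source_lms = ph$landmarks_a, phi = zf)
  expect_true(all(c("mi", "ssim", "dsc_percent", "hd95_mm",
                    "rvd_abs_percent", "voe_percent", "tre_mm") %in%
                    names(panel)))
  expect_true(panel$dsc_percent >= 0 && panel$dsc_percent <= 100)
  expect_true(panel$voe_percent >= 0 && panel$voe_percent <= 100)
  expect_gte(panel$hd95_mm, 0)
  expect_gte(min(panel$tre_mm), 0)
})
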
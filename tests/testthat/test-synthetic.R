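# Phantom generator: determinism, geometry/label consistency, landmark
# correspondence, deformation quality and on-disk round trips. Most
# checks run on a reduced 32x32x24 grid to stay fast; full-size
# behaviour is exercised by the acceptance suite.

small_cfg <- function(...) phantom_config(size = c(32L, 32L, 24L), ...)

test_that("the generator is deterministic given its seed", {
  a <- suppressWarnings(generate_phantom(small_cfg(seed = 5)))
  b <- suppressWarnings(generate_phantom(small_cfg(seed = 5)))
  expect_identical(a$vol_a$data, b$vol_a$data)
  expect_identical(a$vol_b$data, b$vol_b$data)
  expect_identical(a$phi_true$data, b$phi_true$data)
  expect_identical(a$landmarks_b, b$landmarks_b)
  c2 <- suppressWarnings(generate_phantom(small_cfg(seed = 6)))
  expect_false(identical(a$vol_a$data, c2$vol_a$data))
})

test_that("zero amplitude yields a pure intensity re-mapping", {
  ph <- generate_phantom(small_cfg(seed = 9, amplitude = 0))
  expect_identical(ph$phi_true$data, zero_field(c(32, 32, 24))$data)
  expect_equal(dsc(ph$label_organ_a, ph$label_organ_b), 100)
  expect_equal(dsc(ph$label_lesion_a, ph$label_lesion_b), 100)
  # landmark pairs coincide
  expect_equal(ph$landmarks_b$x, ph$landmarks_a$x, tolerance = 1e-9)
})

test_that("lesion contrast is inverted between the modalities", {
  ph <- generate_phantom(small_cfg(seed = 9, amplitude = 0))
  les <- ph$label_lesion_a$data == 1L
  expect_gt(sum(les), 20)
  expect_lt(stats::cor(ph$vol_a$data[les], ph$vol_b$data[les]), 0)
  # lesion darker than organ in A, brighter in B
  org <- ph$label_organ_a$data == 1L & !les
  expect_lt(mean(ph$vol_a$data[les]), mean(ph$vol_a$data[org]))
  expect_gt(mean(ph$vol_b$data[les]), mean(ph$vol_b$data[org]))
})

test_that("ground-truth deformation is smooth, bounded and fold-free", {
  phi <- suppressWarnings(generate_deformation(small_cfg(seed = 3)))
  m <- sqrt(phi$data[, , , 1]^2 + phi$data[, , , 2]^2 +
              phi$data[, , , 3]^2)
  expect_lte(max(m), small_cfg()$amplitude + 1e-9)
  expect_equal(jacobian_report(phi)$folding_count, 0L)
  # boundary taper: zero displacement on the faces
  expect_equal(max(abs(phi$data[1, , , ])), 0)
  expect_equal(max(abs(phi$data[, , 24, ])), 0)
  expect_identical(
    suppressWarnings(generate_deformation(small_cfg(seed = 3)))$data,
    phi$data)
  expect_identical(generate_deformation(small_cfg(seed = 3,
                                                  amplitude = 0))$data,
                   zero_field(c(32, 32, 24))$data)
})

test_that("landmark pairs correspond exactly through the true field", {
  ph <- small_phantom()
  # mapping a deformed-frame landmark through phi_true lands on its
  # undeformed-frame partner (fixed-point construction)
  t_thru <- tre(ph$landmarks_a, ph$landmarks_b, ph$phi_true)
  expect_lt(max(t_thru$tre_mm), 0.5 * max(ph$vol_a$spacing))
  # with no registration, the TRE equals |phi_true| at the deformed-frame
  # landmark positions (unit spacing)
  zf <- zero_field(dim(ph$vol_a$data))
  t0 <- tre(ph$landmarks_b, ph$landmarks_a, zf)
  qb <- phys_to_voxel(ph$phi_true,
                      as.matrix(ph$landmarks_b[, c("x", "y", "z")]))
  disp <- sapply(1:3, function(c)
    macmind:::trilinear3d(ph$phi_true$data[, , , c], qb[, 1], qb[, 2],
                          qb[, 3]))
  expect_equal(t0$tre_mm, sqrt(rowSums(matrix(disp, ncol = 3)^2)),
               tolerance = 1e-6)
  expect_gt(mean(t0$tre_mm), 0)
})

test_that("labels derive from one geometry and lesion sits inside organ", {
  ph <- small_phantom()
  expect_true(all(ph$label_organ_a$data[ph$label_lesion_a$data == 1L] == 1L))
  expect_true(all(ph$label_organ_b$data[ph$label_lesion_b$data == 1L] == 1L))
  expect_equal(nrow(ph$landmarks_a), 8L)
  expect_setequal(ph$landmarks_a$id, ph$landmarks_b$id)
})

test_that("phantom cases round-trip through a directory with a manifest", {
  dir <- withr::local_tempdir()
  ph <- small_phantom()
  write_phantom(ph, dir)
  files <- c("vol_a.nii.gz", "vol_b.nii.gz", "label_organ_a.nii.gz",
             "label_lesion_a.nii.gz", "label_organ_b.nii.gz",
             "label_lesion_b.nii.gz", "phi_true.nii.gz",
             "landmarks_a.csv", "landmarks_b.csv")
  expect_true(all(file.exists(file.path(dir, files))))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_phantom(dir)
  expect_equal(back$vol_a$data, ph$vol_a$data, tolerance = 1e-6)
  expect_identical(back$label_organ_a$data, ph$label_organ_a$data)
  expect_equal(back$landmarks_b$x, ph$landmarks_b$x, tolerance = 1e-9)
  # regenerating from the manifest reproduces the case bit-identically
  regen <- suppressWarnings(generate_phantom(back$config))
  expect_identical(regen$vol_a$data, ph$vol_a$data)
  expect_identical(regen$phi_true$data, ph$phi_true$data)
})

test_that("descriptor space is far more modality-stable than intensity", {
  # the operational meaning of a modality-independent descriptor: on an
  # undeformed phantom pair, channel-wise descriptor discrepancy is
  # smaller than min-max normalized intensity discrepancy
  ph <- generate_phantom(small_cfg(seed = 21, amplitude = 0))
  n01 <- function(x) { r <- range(x); (x - r[1]) / (r[2] - r[1]) }
  cfg <- descriptor_config()
  fa <- suppressWarnings(macmind(ph$vol_a, cfg))
  fb <- suppressWarnings(macmind(ph$vol_b, cfg))
  d_desc <- mean((fa$data - fb$data)^2)
  d_int <- mean((n01(ph$vol_a$data) - n01(ph$vol_b$data))^2)
  expect_lt(d_desc, d_int)
})

test_that("phantom configuration is validated", {
  expect_error(phantom_config(size = c(8, 8, 8)), "at least 16")
  expect_error(phantom_config(amplitude = -1), "amplitude")
  expect_error(phantom_config(sigma = 0), "sigma")
  expect_error(phantom_config(n_landmarks = 1), "n_landmarks")
})
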
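test_that("volume NIfTI round-trip preserves data and spacing", {
  dir <- withr::local_tempdir()
  v <- rand_vol(c(8, 8, 8), seed = 3, spacing = c(1.146, 1.146, 3.0))
  p <- file.path(dir, "v.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_equal(v2$data, v$data, tolerance = 1e-7)
  expect_equal(v2$spacing, c(1.146, 1.146, 3.0), tolerance = 1e-6)

  z <- mac_volume(array(0, c(4, 4, 4)), spacing = c(0.664, 0.664, 5.0))
  pz <- file.path(dir, "z.nii.gz")
  write_volume(z, pz)
  z2 <- read_volume(pz)
  expect_identical(z2$data, z$data)
  expect_equal(z2$spacing, c(0.664, 0.664, 5.0), tolerance = 1e-6)
})

test_that("float32 volumes round-trip bit-identically", {
  dir <- withr::local_tempdir()
  set.seed(9)
  raw <- array(runif(512), c(8, 8, 8))
  # push through one float32 write/read, then again: second trip must be
  # exactly the identity
  p <- file.path(dir, "a.nii.gz")
  write_volume(mac_volume(raw), p)
  once <- read_volume(p)
  write_volume(once, p)
  twice <- read_volume(p)
  expect_identical(twice$data, once$data)
})

test_that("displacement fields round-trip as 4D NIfTI", {
  dir <- withr::local_tempdir()
  set.seed(4)
  phi <- mac_field(array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3)),
                   spacing = c(1, 1, 2))
  p <- file.path(dir, "phi.nii.gz")
  write_field(phi, p)
  phi1 <- read_field(p)
  write_field(phi1, p)
  phi2 <- read_field(p)
  expect_identical(phi2$data, phi1$data)
  expect_equal(phi1$spacing, c(1, 1, 2))
  expect_equal(dim(phi1$data), c(4L, 4L, 4L, 3L))
})

test_that("volume contract errors are raised", {
  dir <- withr::local_tempdir()
  img2d <- RNifti::asNifti(matrix(0, 4, 4))
  p2d <- file.path(dir, "flat.nii.gz")
  RNifti::writeNifti(img2d, p2d)
  expect_error(read_volume(p2d), "expected 3 spatial dimensions")
  expect_error(read_volume(file.path(dir, "missing.nii.gz")), "not found")
  expect_error(mac_volume(array(c(NaN, 1:7), c(2, 2, 2))), "NaN")
  expect_error(mac_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  nan_img <- RNifti::asNifti(array(c(NaN, runif(26)), c(3, 3, 3)))
  pn <- file.path(dir, "nan.nii.gz")
  RNifti::writeNifti(nan_img, pn)
  expect_error(read_volume(pn), "NaN voxels on load: 1")
})

test_that("landmark CSV round-trips, rejects duplicates and bad values", {
  dir <- withr::local_tempdir()
  lm <- mac_landmarks(data.frame(x = c(1.5, 2), y = c(0, -3), z = c(4, 8)),
                      ids = c("a", "b"))
  p <- file.path(dir, "lm.csv")
  write_landmarks(lm, p)
  lm2 <- read_landmarks(p)
  expect_equal(lm2$id, c("a", "b"))
  expect_equal(lm2$x, c(1.5, 2))
  expect_equal(lm2$z, c(4, 8))

  writeLines(c("id,x,y,z", "a,1,2,3", "a,4,5,6"),
             file.path(dir, "dup.csv"))
  expect_error(read_landmarks(file.path(dir, "dup.csv")), "duplicate")
  writeLines(c("id,x,y,z", "a,1,2,oops"), file.path(dir, "bad.csv"))
  expect_error(read_landmarks(file.path(dir, "bad.csv")), "non-numeric")
})

test_that("voxel/physical conversion is an exact inverse pair", {
  v <- mac_volume(array(0, c(5, 6, 7)), spacing = c(1.25, 0.8, 3),
                  origin = c(-10, 4, 2.5))
  idx <- rbind(c(0, 0, 0), c(4, 5, 6), c(1.5, 2.25, 3.5))
  expect_equal(phys_to_voxel(v, voxel_to_phys(v, idx)), idx)
  expect_equal(voxel_to_phys(v, c(0, 0, 0))[1, ], c(-10, 4, 2.5))
})

test_that("label masks keep integer ids through NIfTI", {
  dir <- withr::local_tempdir()
  set.seed(5)
  l <- mac_label(array(sample(0:3, 64, replace = TRUE), c(4, 4, 4)))
  p <- file.path(dir, "l.nii.gz")
  write_label(l, p)
  l2 <- read_label(p)
  expect_identical(l2$data, l$data)
  expect_equal(l2$label_ids, l$label_ids)
})
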
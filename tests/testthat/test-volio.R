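test_that("NIfTI round trip preserves voxels and spacing", {
  v <- ramp_volume(c(4L, 4L, 4L), spacing = c(0.66, 0.66, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$voxels, v$voxels, tolerance = 1e-6)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)

  # a phantom-written fixture with known corner values survives the trip
  ph <- generate_phantom(toy_spec(3L))$volume
  p2 <- tempfile(fileext = ".nii.gz")
  write_volume(ph, p2)
  r2 <- read_volume(p2)
  expect_equal(r2$voxels[1, 1, 1], ph$voxels[1, 1, 1], tolerance = 1e-6)
  expect_equal(max(r2$voxels), 1, tolerance = 1e-6)
  expect_equal(min(r2$voxels), -1, tolerance = 1e-6)
  unlink(c(path, p2))
})

test_that("reading a 2D image is a dimensionality error", {
  path <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(matrix(1:20, 4, 5))
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path), "3D")
  expect_error(read_volume(tempfile()), "not found")
  unlink(path)
})

test_that("volume3d validates its invariants", {
  expect_error(volume3d(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(volume3d(array(0, c(2, 2))), "3D")
  expect_error(volume3d(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(label_mask(array(0.5, c(2, 2, 2))), "0 or 1")
})

test_that("resampling follows the extent arithmetic and identities", {
  v <- volume3d(array(rnorm(10 * 8 * 6), c(10, 8, 6)), spacing = c(1, 1, 1))
  same <- resample_to_spacing(v, c(1, 1, 1))
  expect_identical(same$voxels, v$voxels)

  up <- resample_to_spacing(v, c(0.5, 1, 1))
  expect_equal(dim(up$voxels), c(20L, 8L, 6L))
  expect_equal(up$spacing, c(0.5, 1, 1))

  # round trip via a factor-2 resample returns the original extents
  back <- resample_to_spacing(up, c(1, 1, 1))
  expect_equal(dim(back$voxels), dim(v$voxels))

  konst <- volume3d(array(0.3, c(6, 6, 4)))
  expect_true(all(abs(resample_to_spacing(konst, c(0.7, 1.3, 2))$voxels -
                        0.3) < 1e-12))
  expect_error(resample_to_spacing(v, c(0, 1, 1)), "positive")
})

test_that("center_crop keeps the documented index window and pads with the minimum", {
  v <- volume3d(array(1:(6 * 6 * 6), c(6, 6, 6)))
  cr <- center_crop(v, c(4, 6, 6))
  # n=6, m=4: offset floor((6-4)/2)=1 -> 0-based indices 1..4 (R rows 2..5)
  expect_equal(cr$voxels, v$voxels[2:5, , ])

  idem <- center_crop(cr, c(4, 6, 6))
  expect_identical(idem$voxels, cr$voxels)

  small <- volume3d(array(seq(-1, 1, length.out = 27), c(3, 3, 3)))
  pad <- center_crop(small, c(3, 3, 5))
  expect_equal(dim(pad$voxels), c(3L, 3L, 5L))
  expect_true(all(pad$voxels[, , 1] == -1))   # one low-side layer at the min
  expect_true(all(pad$voxels[, , 5] == -1))   # one high-side layer
  expect_equal(pad$voxels[, , 2:4], small$voxels)

  # odd padding: extra voxel goes to the high side
  pad2 <- center_crop(small, c(3, 3, 6))
  expect_equal(pad2$voxels[, , 2:4], small$voxels)
  expect_true(all(pad2$voxels[, , c(1, 5, 6)] == -1))
})

test_that("resize preserves linear ramps, constants and physical extent", {
  v <- ramp_volume(c(8L, 4L, 4L))
  expect_equal(resize_volume(v, c(8, 4, 4))$voxels, v$voxels,
               tolerance = 1e-12)

  ramp <- volume3d(array(rep(seq(0, 1, length.out = 8), times = 16),
                         c(8, 4, 4)), spacing = c(2, 1, 1))
  r2 <- resize_volume(ramp, c(16, 4, 4))
  expect_equal(r2$voxels[, 1, 1], seq(0, 1, length.out = 16),
               tolerance = 1e-6)
  expect_equal(r2$spacing[1], 1)   # 8 voxels at 2 mm -> 16 voxels at 1 mm

  konst <- volume3d(array(0.7, c(5, 5, 5)))
  expect_true(all(abs(resize_volume(konst, c(9, 3, 7))$voxels - 0.7) < 1e-12))
})

test_that("Hounsfield conversion is the stated linear map", {
  v <- volume3d(array(1024, c(2, 2, 2)))
  expect_true(all(hu_convert(v, 1, -1024)$voxels == 0))
  expect_equal(hu_convert(v, 1, 0)$voxels, v$voxels)
  a <- volume3d(array(rnorm(8), c(2, 2, 2)))
  b <- volume3d(array(rnorm(8), c(2, 2, 2)))
  expect_equal(hu_convert(volume3d(a$voxels + b$voxels), 2, -5)$voxels,
               hu_convert(a, 2, -5)$voxels + hu_convert(b, 2, -5)$voxels + 5)
})

test_that("min-max normalization maps endpoints and handles constants", {
  v <- volume3d(array(c(0, 50, 100, 50, 0, 100, 50, 50), c(2, 2, 2)))
  n <- minmax_normalize(v)
  expect_equal(sort(unique(as.vector(n$voxels))), c(-1, 0, 1))
  expect_equal(min(n$voxels), -1)
  expect_equal(max(n$voxels), 1)
  konst <- minmax_normalize(volume3d(array(5, c(2, 2, 2))))
  expect_true(all(konst$voxels == 0))
  expect_error(minmax_normalize(v, 1, -1), "out_lo < out_hi")
})

test_that("flips are seeded, involutive and axis-correct", {
  v <- ramp_volume(c(4L, 3L, 2L))
  set.seed(1); expect_identical(random_flip(v, 1, p = 0)$voxels, v$voxels)
  f <- flip_axis(v, 1)
  expect_equal(f$voxels[1, , ], v$voxels[4, , ])
  expect_identical(flip_axis(f, 1)$voxels, v$voxels)
  expect_error(random_flip(v, 4), "axis")
  set.seed(7); a <- random_flip(v, 1, 0.5)
  set.seed(7); b <- random_flip(v, 1, 0.5)
  expect_identical(a$voxels, b$voxels)
})

test_that("bilateral split follows the floor/ceil column convention", {
  v <- volume3d(array(rnorm(6 * 256 * 2), c(6, 256, 2)))
  h <- split_bilateral(v)
  expect_equal(dim(h$left$voxels)[2], 128L)
  expect_equal(dim(h$right$voxels)[2], 128L)
  recon <- array(0, dim(v$voxels))
  recon[, 1:128, ] <- h$left$voxels
  recon[, 129:256, ] <- h$right$voxels
  expect_identical(recon, v$voxels)

  odd <- volume3d(array(1:(2 * 5 * 2), c(2, 5, 2)))
  ho <- split_bilateral(odd)
  expect_equal(dim(ho$left$voxels)[2], 2L)
  expect_equal(dim(ho$right$voxels)[2], 2L)
  expect_identical(ho$left$voxels, odd$voxels[, 1:2, , drop = FALSE])
  expect_identical(ho$right$voxels, odd$voxels[, 4:5, , drop = FALSE])
  expect_error(split_bilateral(volume3d(array(0, c(2, 1, 2)))), "width")
})

test_that("the CT preprocessing chain is deterministic at reduced scale", {
  run_chain <- function() {
    v <- generate_phantom(phantom_spec(shape = c(48L, 48L, 24L), seed = 42L))$volume
    v$spacing <- c(0.8, 0.8, 2.5)
    v <- resample_to_spacing(v, c(1, 1, 1))
    v <- hu_convert(v, 1000, -1024)
    v <- center_crop(v, c(40L, 40L, 40L))
    v <- resize_volume(v, c(16L, 16L, 16L))
    minmax_normalize(v)
  }
  a <- run_chain(); b <- run_chain()
  expect_identical(a$voxels, b$voxels)
  expect_true(all(is.finite(a$voxels)))
  expect_equal(range(a$voxels), c(-1, 1))
})
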
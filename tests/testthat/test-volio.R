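# Volume I/O, smoothing and array cropping.

test_that("NIfTI round trip is bit exact and keeps the voxel size", {
  set.seed(1)
  v <- voxel_volume(array(rnorm(32^3), dim = c(32, 32, 32)), 0.115)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(as.numeric(v2$data), as.numeric(v$data))
  expect_equal(v2$voxel_size, 0.115, tolerance = 1e-6)
})

test_that("Analyze 7.5 round trip is bit exact and cross-format consistent", {
  set.seed(2)
  v <- voxel_volume(array(rnorm(20^3), dim = c(20, 20, 20)), 0.115)
  stem <- tempfile()
  write_volume(v, paste0(stem, ".hdr"))
  v2 <- read_volume(paste0(stem, ".hdr"))
  expect_identical(as.numeric(v2$data), as.numeric(v$data))
  expect_equal(v2$voxel_size, 0.115, tolerance = 1e-6)
  # same array via NIfTI
  f <- tempfile(fileext = ".nii")
  write_volume(v, f)
  v3 <- read_volume(f)
  expect_identical(as.numeric(v3$data), as.numeric(v2$data))
})

test_that("an Analyze pair with a missing .img is rejected", {
  set.seed(3)
  v <- voxel_volume(array(rnorm(8^3), dim = c(8, 8, 8)), 0.2)
  stem <- tempfile()
  write_volume(v, paste0(stem, ".hdr"))
  file.remove(paste0(stem, ".img"))
  expect_error(read_volume(paste0(stem, ".hdr")), "missing")
})

test_that("anisotropic voxels are rejected on read", {
  a <- array(0, dim = c(8, 8, 8))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(0.1, 0.1, 0.2)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "anisotropic")
})

test_that("voxel_volume validates its invariants", {
  expect_error(voxel_volume(matrix(0, 2, 2), 0.1), "3D")
  expect_error(voxel_volume(array(0, c(2, 2, 2)), -1), "positive")
})

test_that("gaussian smoothing preserves identity, DC level and mean", {
  set.seed(4)
  v <- voxel_volume(array(rnorm(24^3, 100, 10), dim = rep(24, 3)), 0.115)
  expect_identical(gaussian_smooth(v, 0)$data, v$data)
  const <- voxel_volume(array(7, dim = rep(10, 3)), 0.115)
  expect_equal(gaussian_smooth(const, 0.1)$data, const$data, tolerance = 1e-12)
  sm <- gaussian_smooth(v, 0.1)
  expect_lt(abs(mean(sm$data) - mean(v$data)) / mean(v$data), 0.001)
})

test_that("a delta impulse smooths to the discrete Gaussian kernel", {
  n <- 21
  a <- array(0, dim = rep(n, 3))
  a[11, 11, 11] <- 1
  vs <- 0.115
  sm <- gaussian_smooth(voxel_volume(a, vs), kernel_mm = 0.1)
  sigma <- 0.1 / vs
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  along <- sm$data[(11 - r):(11 + r), 11, 11]
  expect_equal(along, k * k[r + 1]^2, tolerance = 1e-10)
})

test_that("FWHM interpretation of the kernel is available", {
  set.seed(5)
  v <- voxel_volume(array(rnorm(16^3), dim = rep(16, 3)), 0.115)
  s1 <- gaussian_smooth(v, 0.2, kernel_is_fwhm = TRUE)
  s2 <- gaussian_smooth(v, 0.2 / (2 * sqrt(2 * log(2))))
  expect_equal(s1$data, s2$data, tolerance = 1e-12)
  expect_true(s1$meta$smoothing$kernel_is_fwhm)
})

test_that("cropping from the manifest reproduces the constructed layout", {
  arr <- assemble_array(sixteen_eyes(700), voxel_size = 0.45)
  res <- crop_eyes(arr$volume, layout = arr$layout)
  expect_length(res$eyes, 16)
  expect_equal(res$manifest$eye_id, 1:16)
  # each crop contains exactly one bright lens component
  for (i in c(1, 7, 16)) {
    bright <- res$eyes[[i]]$data > 150
    expect_gt(sum(bright), 20)
  }
})

test_that("automatic cropping recovers the generating manifest", {
  arr <- assemble_array(sixteen_eyes(710), voxel_size = 0.45, snr = 25,
                        seed = 4)
  res <- crop_eyes(arr$volume)
  expect_equal(res$manifest$eye_id, 1:16)
  m <- merge(arr$manifest, res$manifest, by = "eye_id")
  expect_equal(m$cell_i.x, m$cell_i.y)
  expect_equal(m$cell_j.x, m$cell_j.y)
  expect_equal(m$cell_k.x, m$cell_k.y)
  expect_equal(m$orientation.x, m$orientation.y)
})

test_that("an array with a deleted eye reports the globe count", {
  arr <- assemble_array(sixteen_eyes(720), voxel_size = 0.45)
  vol <- arr$volume
  b <- arr$manifest[1, ]
  vol$data[(b$x0 + 1):b$x1, (b$y0 + 1):b$y1, (b$z0 + 1):b$z1] <-
    eye_spec(lens_spec(3, 3.4, 2.4))$intensities[["background"]]
  expect_error(crop_eyes(vol), "15")
})

test_that("an in-plane rotation of the array is undone via the inverted eye", {
  arr <- assemble_array(sixteen_eyes(730), voxel_size = 0.45)
  d <- dim(arr$volume$data)
  # rotate the whole volume 90 degrees about z: (x, y) -> (y, nx + 1 - x)
  rot <- aperm(arr$volume$data, c(2, 1, 3))[, rev(seq_len(d[1])), ]
  vol_rot <- voxel_volume(rot, arr$volume$voxel_size)
  res <- crop_eyes(vol_rot)
  expect_equal(sort(res$manifest$eye_id), 1:16)
  inv <- res$manifest[res$manifest$orientation == "inverted", ]
  expect_equal(inv$eye_id, 16L)
  expect_equal(c(inv$cell_i, inv$cell_j, inv$cell_k), c(2L, 2L, 4L))
})
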
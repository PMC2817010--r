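# Threshold selection, flood fill and mask repair.

make_two_level <- function(seed = 1, noise_sd = 0) {
  # bright ball (lens 200) inside background 50
  set.seed(seed)
  n <- 31
  a <- array(50, dim = rep(n, 3))
  ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  inside <- rowSums(sweep(co, 2, rep(ctr, 3))^2) <= 8^2
  a[inside] <- 200
  if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd)
  voxel_volume(array(a, dim = rep(n, 3)), 0.115)
}

test_that("Otsu separates a two-level ROI", {
  vol <- make_two_level()
  thr <- select_threshold(vol, c(16, 16, 16), roi_radius_mm = 1.3)
  expect_gt(thr, 50)
  expect_lt(thr, 200)
})

test_that("a degenerate constant ROI warns and falls back to the midpoint", {
  vol <- voxel_volume(array(100, dim = rep(15, 3)), 0.115)
  expect_warning(thr <- select_threshold(vol, c(8, 8, 8), roi_radius_mm = 0.5),
                 "bimodal")
  expect_equal(as.numeric(thr), 100)
})

test_that("flood fill recovers a noiseless phantom lens volume", {
  lens <- lens_spec(3.0, 3.4, 2.4)
  eye <- eye_spec(lens)
  vol <- voxelize_eye(eye, 0.115, 3, fov = "lens")
  sm <- gaussian_smooth(vol, 0.1)
  seedv <- default_seed(sm)
  thr <- select_threshold(sm, seedv)
  mask <- flood_fill_lens(sm, seedv, thr)
  # within two boundary voxel-shells of the analytic volume
  area <- 2 * pi * (lens$R_a * lens$h_a + lens$R_p * lens$h_p)
  shell <- 2 * area * vol$voxel_size
  expect_lt(abs(mask_volume(mask) - lens$volume), shell)
})

test_that("a seed below the threshold is rejected", {
  vol <- make_two_level()
  expect_error(flood_fill_lens(vol, c(2, 2, 2), threshold = 150),
               "below the threshold")
})

test_that("flood fill respects connectivity between disjoint bright blobs", {
  a <- array(0, dim = c(30, 15, 15))
  a[3:8, 5:10, 5:10] <- 200
  a[20:25, 5:10, 5:10] <- 200
  vol <- voxel_volume(a, 0.115)
  mask <- suppressWarnings(flood_fill_lens(vol, c(5, 7, 7), threshold = 100))
  expect_true(all(which(mask$mask, arr.ind = TRUE)[, 1] <= 8))
})

test_that("a component touching the border is reported as clipped", {
  a <- array(0, dim = c(15, 15, 15))
  a[1:8, 4:10, 4:10] <- 200
  vol <- voxel_volume(a, 0.115)
  expect_error(suppressWarnings(flood_fill_lens(vol, c(4, 7, 7), 100)),
               "clipped")
})

test_that("implausible filled volumes warn", {
  a <- array(0, dim = c(12, 12, 12))
  a[5:7, 5:7, 5:7] <- 200
  vol <- voxel_volume(a, 0.115)
  expect_warning(flood_fill_lens(vol, c(6, 6, 6), 100), "plausibility")
})

test_that("raising the threshold never grows the filled component", {
  vol <- make_two_level(seed = 8, noise_sd = 20)
  seedv <- c(16, 16, 16)
  sizes <- vapply(c(100, 125, 150, 175), function(thr) {
    sum(suppressWarnings(flood_fill_lens(vol, seedv, thr))$mask)
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("repair fills punched voids and is idempotent", {
  lens <- lens_spec(3.0, 3.4, 2.4)
  vol <- voxelize_eye(eye_spec(lens), 0.115, 3, fov = "lens")
  sm <- gaussian_smooth(vol, 0.1)
  seedv <- default_seed(sm)
  mask <- flood_fill_lens(sm, seedv, select_threshold(sm, seedv))
  # punch an interior void
  punched <- mask
  punched$mask[seedv[1] + (-1:1), seedv[2] + (-1:1), seedv[3] + (-1:1)] <- FALSE
  rep1 <- repair_mask(punched)
  expect_true(all(rep1$mask[seedv[1] + (-1:1), seedv[2] + (-1:1),
                            seedv[3] + (-1:1)]))
  rep2 <- repair_mask(rep1)
  expect_identical(rep2$mask, rep1$mask)
  expect_error(repair_mask(new_mask <- {
    m <- mask; m$mask[] <- FALSE; m
  }), "empty")
})

test_that("noisy segmentation reaches the expected overlap with truth", {
  lens <- lens_spec(3.0, 3.4, 2.4)
  eye <- eye_spec(lens)
  vol <- voxelize_eye(eye, 0.115, 3, snr = 10, seed = 17, fov = "lens")
  sm <- gaussian_smooth(vol, 0.1)
  seedv <- default_seed(sm)
  mask <- repair_mask(flood_fill_lens(sm, seedv, select_threshold(sm, seedv)))
  # ground-truth occupancy on the same grid
  d <- dim(vol$data)
  ax <- lapply(1:3, function(i) vol$origin[i] + (seq_len(d[i]) - 1) * 0.115)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  truth <- array(lens_inside(eye$lens, pts), dim = d)
  dice <- 2 * sum(mask$mask & truth) / (sum(mask$mask) + sum(truth))
  expect_gte(dice, 0.98)
})

test_that("default seed lands inside the lens", {
  lens <- lens_spec(3.0, 3.4, 2.4)
  eye <- eye_spec(lens)
  vol <- voxelize_eye(eye, 0.115, 3, snr = 15, seed = 23, fov = "lens")
  sm <- gaussian_smooth(vol, 0.1)
  seedv <- default_seed(sm)
  pt <- vol$origin + (seedv - 1) * vol$voxel_size
  expect_true(lens_inside(eye$lens, matrix(pt, 1)))
})
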
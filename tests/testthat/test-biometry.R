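# Mesh-based lens measurements.

# a clean voxelized-and-wrapped sphere: radius 3 mm
wrapped_sphere <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lens <- lens_spec(3, 3, 6)   # full sphere of radius 3
    eye <- eye_spec(lens, axial_length = 9.4, eq_diameter = 10.4,
                    lens_offset_frac = 0)
    vol <- voxelize_eye(eye, 0.115, 3, fov = "lens")
    sm <- gaussian_smooth(vol, 0.1)
    seedv <- default_seed(sm)
    mask <- repair_mask(flood_fill_lens(sm, seedv, select_threshold(sm, seedv),
                                        volume_bounds_mm3 = c(5, 150)))
    mesh <- smooth_vertices(shrink_wrap(mask, init_mesh(),
                                        intensity = sm), 10)
    cache <<- list(mesh = mesh, lens = eye$lens)
    cache
  }
})

unitize_test <- function(v) v / sqrt(sum(v^2))

test_that("spherical symmetry: thickness 2R for any anterior point", {
  ws <- wrapped_sphere()
  set.seed(31)
  for (k in 1:3) {
    dir <- unitize_test(rnorm(3))
    ant <- ws$lens$center + dir * 3
    ax <- define_axis(ws$mesh, ant, max_surface_dist_mm = 0.3)
    expect_equal(axial_thickness(ws$mesh, ax), 6, tolerance = 0.05)
    expect_equal(equatorial_diameter(ws$mesh, ax), 6, tolerance = 0.08)
  }
})

test_that("sphere fits on a wrapped sphere recover the radius on both sides", {
  ws <- wrapped_sphere()
  ax <- define_axis(ws$mesh, ws$lens$center + c(0, 0, 3))
  fa <- fit_surface_sphere(ws$mesh, ax, "anterior")
  fp <- fit_surface_sphere(ws$mesh, ax, "posterior")
  expect_equal(fa$radius, 3, tolerance = 0.05)
  expect_equal(fp$radius, 3, tolerance = 0.05)
})

test_that("an off-surface anterior point is rejected", {
  ws <- wrapped_sphere()
  expect_error(define_axis(ws$mesh, ws$lens$center + c(0, 0, 4)),
               "from the mesh surface")
})

test_that("automatic axis matches the generating axis of a biconvex phantom", {
  res <- measure_phantom(random_lens(60), snr = 15, seed = 61,
                         true_anterior = FALSE)
  ax <- res$biometry$axis
  cosang <- abs(sum(ax$dir * res$lens$axis))
  expect_gt(cosang, cos(1 * pi / 180))   # within 1 degree
})

test_that("thickness and diameter examples: biconvex and kidney phantoms", {
  b0 <- measure_phantom(lens_spec(3.0, 3.5, 2.4), snr = Inf)$biometry
  expect_equal(b0$thickness_mm, 2.4, tolerance = 0.05)
  kid <- measure_phantom(lens_spec(3.0, 3.5, 2.4, D = 0.4), snr = Inf)$biometry
  expect_equal(kid$thickness_mm, 2.0, tolerance = 0.05)
})

test_that("the degenerate spherical biconvex has equatorial diameter 2 r_e", {
  g <- solve_biconvex_geometry(2, 2, 4)
  expect_equal(2 * g$r_e, 4)
  lens <- lens_spec(2, 2, 4)
  res <- measure_phantom(lens, snr = Inf)
  expect_equal(res$biometry$eq_diam_mm, 4, tolerance = 0.23)
})

test_that("mesh volume of the unit-sphere template is 4*pi/3", {
  mesh <- init_mesh(32768)
  expect_equal(mesh_volume(mesh), 4 * pi / 3, tolerance = 4 * pi / 3 * 0.001)
})

test_that("inward-oriented meshes are sign-corrected with a warning", {
  mesh <- init_mesh(512)
  flipped <- mesh
  flipped$faces <- mesh$faces[, c(1, 3, 2)]
  expect_warning(v <- mesh_volume(flipped), "inward")
  expect_equal(v, mesh_volume(mesh), tolerance = 1e-12)
})

test_that("mesh volume is translation invariant", {
  mesh <- init_mesh(2048)
  moved <- mesh
  moved$vertices <- sweep(mesh$vertices, 2, c(10, -20, 5), `+`)
  expect_equal(mesh_volume(moved), mesh_volume(mesh), tolerance = 1e-9)
})

test_that("an open mesh is rejected by the volume audit", {
  mesh <- init_mesh(128)
  open_mesh <- mesh
  open_mesh$faces <- mesh$faces[-1, , drop = FALSE]
  expect_error(mesh_volume(open_mesh), "closed")
})

test_that("Powell sphere fit matches a dense grid-search optimum", {
  res <- measure_phantom(lens_spec(3.1, 3.5, 2.35), snr = 15, seed = 77)
  mesh <- res$mesh
  ax <- res$biometry$axis
  fit <- fit_surface_sphere(mesh, ax, "anterior")
  pts <- lensmetry:::cone_vertices(mesh, ax$point, ax$dir, 0, 60)
  obj <- function(t) {
    d <- sqrt(rowSums(sweep(pts, 2, ax$point + t * ax$dir)^2))
    sum((d - mean(d))^2)
  }
  # independent zooming grid search on the axis-center parameter
  lo <- -30; hi <- -0.05
  for (z in 1:9) {
    tg <- seq(lo, hi, length.out = 41)
    fg <- vapply(tg, obj, 0)
    k <- which.min(fg)
    lo <- tg[max(1, k - 1)]; hi <- tg[min(41, k + 1)]
  }
  t_grid <- tg[k]
  expect_lt(abs(obj(t_grid) - fit$objective), 1e-8)
})

test_that("sphere fits with too few cone vertices are rejected", {
  ws <- wrapped_sphere()
  ax <- define_axis(ws$mesh, ws$lens$center + c(0, 0, 3))
  expect_error(fit_surface_sphere(ws$mesh, ax, "anterior",
                                  cone_full_angle = 1), "cone")
})

test_that("free-center sphere fit agrees with the constrained fit on a sphere", {
  ws <- wrapped_sphere()
  ax <- define_axis(ws$mesh, ws$lens$center + c(0, 0, 3))
  f1 <- fit_surface_sphere(ws$mesh, ax, "anterior")
  f2 <- fit_surface_sphere(ws$mesh, ax, "anterior", free_center = TRUE)
  expect_equal(f1$radius, f2$radius, tolerance = 0.03)
})

test_that("kidney classification separates biconvex from dented phantoms", {
  b0 <- measure_phantom(lens_spec(3.0, 3.4, 2.4), snr = 15, seed = 81)$biometry
  expect_false(b0$kidney)
  expect_lt(b0$depth_mm, 0.05)
  b1 <- measure_phantom(lens_spec(3.0, 3.4, 2.4, D = 0.4), snr = 15,
                        seed = 82)$biometry
  expect_true(b1$kidney)
  expect_lt(abs(b1$depth_mm - 0.4), 0.1)
})

test_that("biometry rows serialize to a one-row data frame", {
  b <- measure_phantom(random_lens(62), snr = 15, seed = 63)$biometry
  df <- as.data.frame(b)
  expect_equal(nrow(df), 1)
  expect_true(all(c("thickness_mm", "eq_diam_mm", "volume_mm3", "Ra_mm",
                    "Rp_mm", "kidney", "depth_mm") %in% names(df)))
})
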
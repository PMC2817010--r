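# Shared fixtures: all phantom inputs are generated in code at test time.

# Monte-Carlo volume oracle for the two-cap solid (rejection sampling in the
# bounding box). Independent of the analytic cap formulas.
mc_lens_volume <- function(spec, n = 1e6, seed = 1, chunk = 2e6) {
  lo <- c(-spec$r_e, -spec$r_e, -spec$h_p)
  hi <- c(spec$r_e, spec$r_e, spec$h_a)
  boxv <- prod(hi - lo)
  set.seed(seed)
  hits <- 0
  left <- n
  while (left > 0) {
    m <- min(chunk, left)
    pts <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                 runif(m, lo[3], hi[3]))
    hits <- hits + sum(lens_inside(spec, pts))
    left <- left - m
  }
  boxv * hits / n
}

# a random feasible biconvex lens in the study's plausible chick-lens range
random_lens <- function(seed, D = 0, ...) {
  set.seed(seed)
  lens_spec(R_a = runif(1, 2.6, 3.6), R_p = runif(1, 2.9, 3.9),
            T_ax = runif(1, 2.1, 2.6), D = D, ...)
}

# voxelize one eye phantom around the lens and run the full measurement
# chain; returns the biometry plus ground truth
measure_phantom <- function(lens0, snr = 15, seed = 1,
                            config = pipeline_config(), true_anterior = TRUE) {
  eye <- eye_spec(lens0)
  lens <- eye$lens
  vol <- voxelize_eye(eye, voxel_size = config$voxel_size,
                      supersample = config$supersample, snr = snr,
                      seed = seed, fov = "lens")
  ant <- if (true_anterior)
    lens$center + lens$axis * (lens$h_a - lens$D) * lens$shrink else NULL
  res <- analyze_eye_volume(vol, config, anterior_point = ant,
                            orient_hint = lens$axis)
  list(biometry = res$biometry, mask = res$mask, mesh = res$mesh,
       lens = lens, truth = list(
         T_ax = lens_axial_extent(lens), eq_diam = 2 * lens$r_e * lens$shrink,
         volume = lens$volume, R_a = lens$R_a, R_p = lens$R_p, D = lens$D))
}

# small eye suitable for array tests (keeps array grids small)
small_eye <- function(seed, inverted = FALSE) {
  set.seed(seed)
  lens <- lens_spec(runif(1, 2.7, 3.3), runif(1, 3.1, 3.7), runif(1, 2.2, 2.5))
  eye_spec(lens, axial_length = 8.5, eq_diameter = 9.5, inverted = inverted)
}

sixteen_eyes <- function(seed) {
  c(lapply(seq_len(15), function(i) small_eye(seed + i)),
    list(small_eye(seed + 16, inverted = TRUE)))
}

# measure one cohort bird's eye phantom (lens drawn from the cohort model,
# so between-eye variance matches the study population). `reposition = TRUE`
# emulates re-embedding between repeat scans: a small random tilt and a
# sub-voxel translation, so the two scans differ in grid phase and pose,
# not just in noise.
measure_cohort_eye <- function(row, lens0, seed, config = pipeline_config(),
                               reposition = FALSE) {
  axis <- c(0, 0, 1)
  center <- c(0, 0, 0)
  if (reposition) {
    set.seed(child_seed(seed, 999))
    tilt <- runif(1, 0, 5) * pi / 180
    phi <- runif(1, 0, 2 * pi)
    axis <- c(sin(tilt) * cos(phi), sin(tilt) * sin(phi), cos(tilt))
    center <- runif(3, -0.5, 0.5) * config$voxel_size
  }
  eye <- cohort_eye(row, lens0, center = center, axis = axis)
  lens <- eye$lens
  vol <- voxelize_eye(eye, voxel_size = config$voxel_size,
                      supersample = config$supersample, snr = config$snr,
                      seed = seed, fov = "lens")
  ant <- lens$center + lens$axis * (lens$h_a - lens$D) * lens$shrink
  analyze_eye_volume(vol, config, anterior_point = ant,
                     orient_hint = lens$axis)$biometry
}

# anterior surface height (z above the equatorial plane, lens frame) of a
# dented lens at in-plane radius rho, solved from the implicit model
dented_anterior_z <- function(spec, rho) {
  sapply(rho, function(r) {
    cap <- spec$h_a - (spec$R_a - sqrt(spec$R_a^2 - r^2))
    uniroot(function(z) {
      th <- atan2(r, z)
      z + spec$D * exp(-th^2 / (2 * spec$sigma_theta^2)) - cap
    }, c(1e-6, cap + 1e-9))$root
  })
}
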
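## Synthetic eye phantoms: ground-truthed digital eyes for validating every
## stage of the measurement pipeline. An eye is a spheroidal globe (scleral
## shell around humor) containing one lens_spec; phantoms are voxelized by
## supersampled occupancy averaging (partial-volume rendering) and degraded
## with Rician magnitude noise at a stated SNR.

#' Specify a synthetic eye phantom
#'
#' @param lens a [lens_spec()]; its `center`/`axis` are overridden to place
#'   the lens inside the globe along the eye axis.
#' @param axial_length globe axial length (mm).
#' @param eq_diameter globe equatorial diameter (mm).
#' @param center globe center position (mm).
#' @param axis unit vector, anterior direction of the eye.
#' @param intensities named numeric vector with components `lens`, `humor`,
#'   `sclera`, `background` (arbitrary units, pairwise distinct). On the
#'   T2-weighted images of fixed eyes the lens is the bright phase.
#' @param sclera_thickness scleral shell thickness (mm).
#' @param lens_offset_frac position of the lens equatorial plane along the
#'   axis, as a fraction of the axial length anterior of the globe center.
#' @param inverted logical; inverted eyes point their anterior axis the
#'   opposite way in an array (the identification marker of the scan layout).
#' @return an object of class `eye_spec`.
#' @export
eye_spec <- function(lens, axial_length = 9.5, eq_diameter = 10.5,
                     center = c(0, 0, 0), axis = c(0, 0, 1),
                     intensities = c(lens = 200, humor = 100, sclera = 40,
                                     background = 20),
                     sclera_thickness = 0.3, lens_offset_frac = 0.18,
                     inverted = FALSE) {
  stopifnot(inherits(lens, "lens_spec"),
            axial_length > 0, eq_diameter > 0,
            all(c("lens", "humor", "sclera", "background") %in%
                  names(intensities)))
  if (anyDuplicated(intensities[c("lens", "humor", "sclera", "background")]))
    stop("tissue intensity levels must be pairwise distinct")
  axis <- unitize(axis)
  if (inverted) axis <- -axis
  offset <- lens_offset_frac * axial_length
  lens$center <- as.numeric(center) + axis * offset
  lens$axis <- axis
  # lens must fit inside the humor cavity (inner spheroid)
  a_in <- eq_diameter / 2 - sclera_thickness
  c_in <- axial_length / 2 - sclera_thickness
  zmax <- offset + lens$shrink * lens$h_a
  zmin <- offset - lens$shrink * lens$h_p
  rmax <- lens$shrink * lens$r_e
  fits <- function(z, r) (r / a_in)^2 + (z / c_in)^2 < 1
  if (!(fits(zmax, 0) && fits(zmin, 0) && fits(offset, rmax)))
    stop("lens does not fit inside the globe")
  structure(list(lens = lens, axial_length = axial_length,
                 eq_diameter = eq_diameter, center = as.numeric(center),
                 axis = axis, intensities = intensities,
                 sclera_thickness = sclera_thickness, inverted = inverted),
            class = "eye_spec")
}

# tissue class at arbitrary points (n x 3, mm):
# 0 background, 1 sclera, 2 humor, 3 lens
eye_class_at <- function(eye, pts) {
  q <- sweep(pts, 2, eye$center)
  z <- as.numeric(q %*% eye$axis)
  rho2 <- pmax(rowSums(q^2) - z^2, 0)
  a_out <- eye$eq_diameter / 2
  c_out <- eye$axial_length / 2
  a_in <- a_out - eye$sclera_thickness
  c_in <- c_out - eye$sclera_thickness
  cls <- integer(nrow(pts))
  in_out <- rho2 / a_out^2 + z^2 / c_out^2 <= 1
  cls[in_out] <- 1L
  in_in <- rho2 / a_in^2 + z^2 / c_in^2 <= 1
  cls[in_in] <- 2L
  if (any(in_in)) {
    il <- lens_inside(eye$lens, pts[in_in, , drop = FALSE])
    cls[in_in][il] <- 3L
  }
  cls
}

# tissue intensity at arbitrary points (n x 3, mm)
eye_intensity_at <- function(eye, pts) {
  lv <- c(eye$intensities[["background"]], eye$intensities[["sclera"]],
          eye$intensities[["humor"]], eye$intensities[["lens"]])
  lv[eye_class_at(eye, pts) + 1L]
}

#' Voxelize an eye phantom
#'
#' Renders an [eye_spec()] onto an isotropic voxel grid. Partial-volume
#' intensities are produced by supersampled occupancy averaging (each voxel is
#' the mean tissue intensity over `supersample^3` subsamples) and Rician
#' magnitude noise is added at the stated SNR (defined as mean lens intensity
#' divided by the Gaussian channel noise sigma).
#'
#' @param eye an [eye_spec()].
#' @param voxel_size voxel edge length in mm (default 0.115, the scanning
#'   resolution this pipeline targets).
#' @param supersample subsamples per voxel edge (default 5); only voxels on
#'   a tissue interface are supersampled.
#' @param snr signal-to-noise ratio; `Inf` for a noiseless render.
#' @param seed RNG seed for the noise draw (required when `snr` is finite).
#' @param fov `"globe"` renders the whole eye; `"lens"` renders a tight box
#'   around the lens only (the per-eye crop a measurement run works on).
#' @param margin_mm margin around the rendered structure (mm).
#' @return a [voxel_volume()]; ground truth and render settings are stored in
#'   `meta`.
#' @export
voxelize_eye <- function(eye, voxel_size = 0.115, supersample = 5,
                         snr = Inf, seed = NULL, fov = c("globe", "lens"),
                         margin_mm = 1) {
  stopifnot(inherits(eye, "eye_spec"), voxel_size > 0, supersample >= 1)
  fov <- match.arg(fov)
  supersample <- as.integer(supersample)
  lens <- eye$lens
  if (fov == "globe") {
    # conservative: max spheroid half-extent in any direction
    h <- max(eye$eq_diameter, eye$axial_length) / 2 + margin_mm
    lo <- eye$center - h
    hi <- eye$center + h
  } else {
    r <- max(lens$r_e, lens$h_a, lens$h_p) * lens$shrink + margin_mm
    lo <- lens$center - r
    hi <- lens$center + r
  }
  n <- pmax(ceiling((hi - lo) / voxel_size), 1)
  origin <- lo
  # lens must lie inside the field of view
  lhalf <- max(lens$r_e, lens$h_a, lens$h_p) * lens$shrink
  lmax <- lens$center + lhalf
  lmin <- lens$center - lhalf
  if (any(lmin < lo - 1e-9) || any(lmax > lo + n * voxel_size + 1e-9))
    stop("lens exceeds the field of view")
  xs <- origin[1] + (seq_len(n[1]) - 1) * voxel_size
  ys <- origin[2] + (seq_len(n[2]) - 1) * voxel_size
  zs <- origin[3] + (seq_len(n[3]) - 1) * voxel_size
  X <- rep(xs, times = n[2] * n[3])
  Y <- rep(rep(ys, each = n[1]), times = n[3])
  Z <- rep(zs, each = n[1] * n[2])
  lv <- c(eye$intensities[["background"]], eye$intensities[["sclera"]],
          eye$intensities[["humor"]], eye$intensities[["lens"]])
  # two-pass render: classify voxel centers, then supersample only voxels on
  # a tissue interface (a voxel whose 6-neighborhood is single-class is
  # interior and needs no occupancy averaging)
  cls <- array(eye_class_at(eye, cbind(X, Y, Z)), dim = n)
  arr <- array(lv[cls + 1L], dim = n)
  if (supersample > 1) {
    mixed <- array(FALSE, n)
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      sh <- shift3i(cls, s[1], s[2], s[3])
      mixed <- mixed | (!is.na(sh) & sh != cls)
    }
    mixed <- dilate_ball(mixed, 1)
    idx <- which(mixed)
    if (length(idx)) {
      offs <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * voxel_size
      acc <- numeric(length(idx))
      base <- cbind(X[idx], Y[idx], Z[idx])
      for (oz in offs) for (oy in offs) for (ox in offs) {
        acc <- acc + lv[eye_class_at(
          eye, sweep(base, 2, c(ox, oy, oz), `+`)) + 1L]
      }
      arr[idx] <- acc / supersample^3
    }
  }
  meta <- list(eye = eye, supersample = supersample, snr = snr, seed = seed,
               fov = fov)
  if (is.finite(snr)) {
    if (is.null(seed)) stop("a seed is required for a noisy render")
    sigma <- eye$intensities[["lens"]] / snr
    arr <- with_seed(seed, function() rician(arr, sigma))
    meta$noise_sigma <- sigma
  }
  voxel_volume(arr, voxel_size, origin = origin, meta = meta)
}

# Rician magnitude noise: |signal + complex Gaussian|
rician <- function(arr, sigma) {
  n <- length(arr)
  re <- arr + rnorm(n, sd = sigma)
  im <- rnorm(n, sd = sigma)
  array(sqrt(re^2 + im^2), dim = dim(arr))
}

#' Assemble a 2x2x4 eye-array phantom
#'
#' Places 16 eye phantoms on the scanning layout: four 2x2 layers stacked
#' inside a cylindrical agarose block, exactly one eye inverted so that every
#' eye in the resulting image can be identified unambiguously.
#'
#' @param eyes list of exactly 16 [eye_spec()]s, exactly one with
#'   `inverted = TRUE`. Eye ids follow list order: cell
#'   `(i, j, k)` (column, row, layer) holds eye `(k-1)*4 + (j-1)*2 + i`.
#' @param voxel_size,supersample,snr,seed render settings as in
#'   [voxelize_eye()].
#' @param gap_mm clearance between neighbouring globes (mm).
#' @return a list with `volume` (the array [voxel_volume()]) and `manifest`
#'   (layout data frame: eye id, cell, center, orientation, bounding box in
#'   0-based half-open voxel coordinates).
#' @export
assemble_array <- function(eyes, voxel_size = 0.115, supersample = 1,
                           snr = Inf, seed = NULL, gap_mm = 1.5) {
  if (length(eyes) != 16)
    stop(sprintf("an array requires exactly 16 eyes, got %d", length(eyes)))
  stopifnot(all(vapply(eyes, inherits, TRUE, "eye_spec")))
  n_inv <- sum(vapply(eyes, function(e) isTRUE(e$inverted), TRUE))
  if (n_inv != 1)
    stop(sprintf("exactly one eye must be inverted, got %d", n_inv))
  eqd <- vapply(eyes, `[[`, numeric(1), "eq_diameter")
  axl <- vapply(eyes, `[[`, numeric(1), "axial_length")
  pitch_xy <- max(eqd) + gap_mm
  pitch_z <- max(axl) + gap_mm
  cyl_r <- pitch_xy / sqrt(2) + max(eqd) / 2 + gap_mm / 2
  # z range must cover the outer layers' render boxes (cubic, sized by the
  # largest globe dimension)
  box_half <- max(c(eqd, axl)) / 2 + 0.5
  zspan <- 3 * pitch_z + 2 * box_half + 1
  background <- eyes[[1]]$intensities[["background"]]
  cells <- expand.grid(i = 1:2, j = 1:2, k = 1:4)
  cells$eye_id <- (cells$k - 1L) * 4L + (cells$j - 1L) * 2L + cells$i
  cells <- cells[order(cells$eye_id), ]
  centers <- cbind((cells$i - 1.5) * pitch_xy,
                   (cells$j - 1.5) * pitch_xy,
                   (cells$k - 2.5) * pitch_z)
  # grid covering the cylinder
  lo <- c(-cyl_r, -cyl_r, -zspan / 2)
  hi <- c(cyl_r, cyl_r, zspan / 2)
  n <- ceiling((hi - lo) / voxel_size)
  arr <- array(0, dim = n)
  xs <- lo[1] + (seq_len(n[1]) - 1) * voxel_size
  ys <- lo[2] + (seq_len(n[2]) - 1) * voxel_size
  zs <- lo[3] + (seq_len(n[3]) - 1) * voxel_size
  inside_cyl <- outer(xs^2, ys^2, `+`) <= cyl_r^2
  arr[] <- background * as.numeric(rep(as.vector(inside_cyl), times = n[3]))
  manifest <- cells
  manifest$orientation <- "normal"
  boxes <- matrix(0L, 16, 6)
  rendered <- vector("list", 16)
  for (e in seq_len(16)) {
    eye <- eyes[[e]]
    eye$intensities[["background"]] <- background
    # re-anchor the eye (and its lens) at the cell center, axis +/- z
    eye2 <- eye_spec(lens = eye$lens, axial_length = eye$axial_length,
                     eq_diameter = eye$eq_diameter, center = centers[e, ],
                     axis = c(0, 0, 1), intensities = eye$intensities,
                     sclera_thickness = eye$sclera_thickness,
                     inverted = eye$inverted)
    if (sqrt(sum(centers[e, 1:2]^2)) + eye$eq_diameter / 2 > cyl_r)
      stop("eye placement falls outside the agarose cylinder")
    sub <- voxelize_eye(eye2, voxel_size = voxel_size,
                        supersample = supersample, snr = Inf,
                        fov = "globe", margin_mm = 0.4)
    # paste the sub-box into the global grid (tissue voxels only, so the
    # rectangular render box does not stamp agarose over the air outside
    # the cylinder)
    i0 <- round((sub$origin - lo) / voxel_size)
    ds <- dim(sub$data)
    if (any(i0 < 0) || any(i0 + ds > n))
      stop("eye placement falls outside the array volume")
    ii <- (i0[1] + 1):(i0[1] + ds[1])
    jj <- (i0[2] + 1):(i0[2] + ds[2])
    kk <- (i0[3] + 1):(i0[3] + ds[3])
    target <- arr[ii, jj, kk]
    tissue <- sub$data != background
    if (any(target[tissue] > background + 1e-9))
      stop("eye placements overlap")
    if (any(target[tissue] < background - 1e-9))
      stop("eye placement falls outside the agarose cylinder")
    target[tissue] <- sub$data[tissue]
    arr[ii, jj, kk] <- target
    manifest$orientation[e] <- if (eye$inverted) "inverted" else "normal"
    boxes[e, ] <- c(i0, i0 + ds)
    rendered[[e]] <- eye2
  }
  manifest$x0 <- boxes[, 1]; manifest$y0 <- boxes[, 2]; manifest$z0 <- boxes[, 3]
  manifest$x1 <- boxes[, 4]; manifest$y1 <- boxes[, 5]; manifest$z1 <- boxes[, 6]
  if (is.finite(snr)) {
    if (is.null(seed)) stop("a seed is required for a noisy render")
    sigma <- eyes[[1]]$intensities[["lens"]] / snr
    arr <- with_seed(seed, function() rician(arr, sigma))
  }
  vol <- voxel_volume(arr, voxel_size, origin = lo,
                      meta = list(kind = "eye_array", snr = snr, seed = seed))
  list(volume = vol, manifest = manifest, layout = list(cells = manifest),
       eyes = rendered)
}

#' Write an array layout manifest as JSON
#'
#' @param layout the `manifest` data frame from [assemble_array()] or
#'   [crop_eyes()].
#' @param path destination `.json` path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(layout, path) {
  jsonlite::write_json(layout, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
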
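## Lens segmentation: local Otsu threshold selection, 26-connected flood
## fill from a seed, and automated mask repair (morphological closing,
## per-slice 2D hole filling, 3D cavity filling) replacing the manual
## slice-by-slice editing of the original workflow.

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance over a 256-bin histogram. Returns `NA`
#' for (near-)constant input.
#'
#' @param values numeric vector of intensities.
#' @param nbins histogram bins.
#' @return the threshold (a value strictly between `min` and `max`), or `NA`.
#' @export
otsu_threshold <- function(values, nbins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) <= 0) return(NA_real_)
  h <- tabulate(pmin(pmax(
    findInterval(values, seq(rng[1], rng[2], length.out = nbins + 1),
                 rightmost.closed = TRUE), 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, nbins)
  bc[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  k <- which.max(bc)
  # midpoint between the chosen bin and the next
  rng[1] + k * diff(rng) / nbins
}

#' Select a lens/background threshold in a region of interest
#'
#' Applies Otsu's method within a spherical ROI around the seed point, where
#' the local histogram (lens vs surrounding humor) is strongly bimodal.
#'
#' @param vol a [voxel_volume()].
#' @param seed integer voxel coordinates (1-based, length 3) inside the lens.
#' @param roi_radius_mm ROI radius; default 1.5 x the expected lens
#'   equatorial radius.
#' @param lens_radius_mm expected lens equatorial radius (mm), used only for
#'   the default ROI size.
#' @return the threshold intensity. If the ROI histogram is effectively
#'   unimodal a warning is raised and the midpoint of the ROI intensity range
#'   is returned.
#' @export
select_threshold <- function(vol, seed, roi_radius_mm = NULL,
                             lens_radius_mm = 2.45) {
  stopifnot(inherits(vol, "voxel_volume"), length(seed) == 3)
  d <- dim(vol$data)
  seed <- as.integer(round(seed))
  if (any(seed < 1) || any(seed > d)) stop("seed lies outside the volume")
  r_mm <- roi_radius_mm %||% (1.5 * lens_radius_mm)
  r_vox <- r_mm / vol$voxel_size
  lo <- pmax(seed - ceiling(r_vox), 1L)
  hi <- pmin(seed + ceiling(r_vox), d)
  sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  ctr <- seed - lo + 1L
  dist2 <- outer(outer((seq_len(ds[1]) - ctr[1])^2,
                       (seq_len(ds[2]) - ctr[2])^2, `+`),
                 (seq_len(ds[3]) - ctr[3])^2, `+`)
  roi <- sub[dist2 <= r_vox^2]
  rng <- range(roi)
  tot_var <- var(roi)
  thr <- otsu_threshold(roi)
  bimodal <- FALSE
  if (!is.na(thr) && is.finite(tot_var) && tot_var > 0) {
    g1 <- roi[roi <= thr]; g2 <- roi[roi > thr]
    if (length(g1) && length(g2)) {
      w1 <- length(g1) / length(roi)
      between <- w1 * (1 - w1) * (mean(g2) - mean(g1))^2
      bimodal <- between / tot_var > 0.1
    }
  }
  if (!bimodal) {
    warning("ROI histogram is not separably bimodal; falling back to the midpoint threshold")
    thr <- mean(rng)
    if (rng[1] == rng[2]) return(thr)
    return(min(max(thr, rng[1] + 1e-12), rng[2] - 1e-12))
  }
  thr <- min(max(thr, rng[1] + 1e-12), rng[2] - 1e-12)
  # robust class plateau levels, estimated away from the partial-volume
  # boundary band; the operational threshold is their midpoint, which is
  # where a partial-volume boundary voxel is exactly half lens (Otsu's
  # discriminant splits the classes but sits off-center when the classes
  # have unequal populations, which would bias every volume downstream)
  hi <- roi[roi > thr]; lo <- roi[roi <= thr]
  levels <- c(inside = as.numeric(quantile(hi, 0.6, names = FALSE)),
              outside = as.numeric(quantile(lo, 0.4, names = FALSE)))
  thr <- min(max(mean(levels), rng[1] + 1e-12), rng[2] - 1e-12)
  attr(thr, "class_levels") <- levels
  thr
}

#' Flood fill the lens from a seed voxel
#'
#' Extracts the 26-connected component of supra-threshold voxels containing
#' the seed. The lens is the bright phase on T2-weighted images of fixed
#' eyes; pass `polarity = "dark"` for inverted contrast.
#'
#' @param vol a [voxel_volume()].
#' @param seed integer voxel coordinates (1-based) inside the lens.
#' @param threshold intensity threshold, e.g. from [select_threshold()].
#' @param polarity `"bright"` (fill `>= threshold`) or `"dark"`.
#' @param volume_bounds_mm3 plausibility range for the filled volume; a
#'   warning is raised outside it.
#' @return an object of class `lens_mask`: logical array `mask` plus the
#'   voxel size, seed and threshold used.
#' @export
flood_fill_lens <- function(vol, seed, threshold, polarity = c("bright", "dark"),
                            volume_bounds_mm3 = c(5, 100)) {
  stopifnot(inherits(vol, "voxel_volume"), length(seed) == 3)
  polarity <- match.arg(polarity)
  d <- dim(vol$data)
  seed <- as.integer(round(seed))
  if (any(seed < 1) || any(seed > d)) stop("seed lies outside the volume")
  sval <- vol$data[seed[1], seed[2], seed[3]]
  phase <- if (polarity == "bright") vol$data >= threshold else vol$data <= threshold
  if (!phase[seed[1], seed[2], seed[3]])
    stop(sprintf("seed intensity %.3g is below the threshold %.3g", sval, threshold))
  lin <- seed[1] + (seed[2] - 1L) * d[1] + (seed[3] - 1L) * d[1] * d[2]
  comp <- .flood_fill_cc(phase, as.integer(lin), 26L)
  if (touches_border(comp))
    stop("lens clipped: flood-filled component touches the volume border")
  v_mm3 <- sum(comp) * vol$voxel_size^3
  if (v_mm3 < volume_bounds_mm3[1] || v_mm3 > volume_bounds_mm3[2])
    warning(sprintf("filled volume %.1f mm^3 outside plausibility bounds [%g, %g]",
                    v_mm3, volume_bounds_mm3[1], volume_bounds_mm3[2]))
  new_lens_mask(comp, vol, seed, threshold)
}

#' Coerce a volume to a lens mask
#'
#' Interprets a (typically uint8) volume as a binary mask, e.g. one written
#' earlier with [write_mask()].
#'
#' @param vol a [voxel_volume()].
#' @param threshold voxels above this value are mask members.
#' @return a `lens_mask`.
#' @export
as_lens_mask <- function(vol, threshold = 0.5) {
  stopifnot(inherits(vol, "voxel_volume"))
  m <- vol$data > threshold
  if (!any(m)) stop("mask is empty")
  idx <- arrayInd(which(m), dim(m))
  seed <- as.integer(round(colMeans(idx)))
  new_lens_mask(m, vol, seed, threshold)
}

new_lens_mask <- function(mask, vol, seed, threshold) {
  structure(list(mask = mask, voxel_size = vol$voxel_size,
                 origin = vol$origin, seed = seed, threshold = threshold),
            class = "lens_mask")
}

#' @export
print.lens_mask <- function(x, ...) {
  cat(sprintf("lens_mask: %d voxels (%.2f mm^3) @ %.4f mm, threshold %.3g\n",
              sum(x$mask), sum(x$mask) * x$voxel_size^3, x$voxel_size,
              x$threshold))
  invisible(x)
}

touches_border <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
}

#' Repair a segmented lens mask
#'
#' Automates the manual slice-checking step: 3D morphological closing with a
#' ball element (removes noise pinholes at the surface), 2D hole filling in
#' every slice along the chosen axis, 3D cavity filling, and reduction to the
#' largest 26-connected component. Idempotent.
#'
#' @param mask a `lens_mask`.
#' @param closing_radius ball radius in voxels for the closing (default 2).
#' @param axis slice normal for the 2D hole fill (1, 2 or 3). Slices must
#'   not be perpendicular to the optical axis: an anterior "kidney"
#'   depression is enclosed in-plane in such slices and would be filled as
#'   if it were a hole. The default (1) is orthogonal to this package's
#'   phantom/array convention of eyes pointing along z.
#' @return the repaired `lens_mask`.
#' @export
repair_mask <- function(mask, closing_radius = 2, axis = 1) {
  stopifnot(inherits(mask, "lens_mask"))
  m <- mask$mask
  if (!any(m)) stop("cannot repair an empty mask")
  if (closing_radius > 0) {
    m <- dilate_ball(m, closing_radius)
    m <- !dilate_ball(!m, closing_radius)
  }
  m <- fill_holes_slices(m, axis = axis)
  m <- fill_cavities(m)
  lab <- .label_cc(m, 26L)
  if (max(lab) > 1) {
    keep <- which.max(tabulate(lab))
    m <- array(lab == keep, dim = dim(m))
  }
  out <- mask
  out$mask <- m
  out
}

# binary dilation with a discrete ball of given voxel radius
dilate_ball <- function(m, r) {
  d <- dim(m)
  out <- m
  rr <- floor(r)
  for (dz in -rr:rr) for (dy in -rr:rr) for (dx in -rr:rr) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx^2 + dy^2 + dz^2 > r^2) next
    out <- out | shift3(m, dx, dy, dz)
  }
  out
}

shift3 <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

# fill 2D holes (background regions not connected to the slice border)
# in every slice perpendicular to `axis`
fill_holes_slices <- function(m, axis = 3) {
  d <- dim(m)
  perm <- c(setdiff(1:3, axis), axis)
  a <- aperm(m, perm)
  da <- dim(a)
  for (k in seq_len(da[3])) {
    sl <- a[, , k]
    if (!any(sl)) next
    bg <- !sl
    dim(bg) <- c(da[1], da[2])
    lab <- .label_cc(bg, 6L)  # 4-connectivity in 2D
    border <- unique(c(lab[1, ], lab[da[1], ], lab[, 1], lab[, da[2]]))
    border <- border[border > 0]
    hole <- bg & !(lab %in% border)
    if (any(hole)) {
      sl[hole] <- TRUE
      a[, , k] <- sl
    }
  }
  aperm(a, order(perm))
}

# fill fully enclosed 3D cavities
fill_cavities <- function(m) {
  bg <- !m
  lab <- .label_cc(bg, 6L)
  d <- dim(m)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  hole <- bg & !array(lab %in% border, d)
  m | hole
}

#' Voxel-count volume of a lens mask
#'
#' @param mask a `lens_mask`.
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "lens_mask"))
  sum(mask$mask) * mask$voxel_size^3
}

#' Default lens seed: brightest centroid-proximal voxel of the main bright
#' component
#'
#' Reproduces the operator's seed click: global Otsu threshold, largest
#' 26-connected bright component, then the brightest voxel among those close
#' to the component centroid.
#'
#' @param vol a [voxel_volume()] (ideally pre-smoothed).
#' @param top_quantile voxels of the component at or above this intensity
#'   quantile are seed candidates.
#' @return integer voxel coordinates (length 3).
#' @export
default_seed <- function(vol, top_quantile = 0.9) {
  stopifnot(inherits(vol, "voxel_volume"))
  thr <- otsu_threshold(as.numeric(vol$data))
  if (is.na(thr)) stop("volume is constant; cannot pick a seed")
  bright <- vol$data > thr
  lab <- .label_cc(bright, 26L)
  if (max(lab) == 0) stop("no bright component found")
  keep <- which.max(tabulate(lab))
  idx <- which(lab == keep)
  co <- arrayInd(idx, dim(vol$data))
  vals <- vol$data[idx]
  cand <- vals >= quantile(vals, top_quantile)
  co <- co[cand, , drop = FALSE]
  ctr <- colMeans(co)
  best <- which.min(rowSums(sweep(co, 2, ctr)^2))
  as.integer(co[best, ])
}

#' Write a lens mask as NIfTI (uint8)
#'
#' @param mask a `lens_mask`.
#' @param path destination `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lens_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  vs <- mask$voxel_size
  RNifti::pixdim(img) <- c(vs, vs, vs)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
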
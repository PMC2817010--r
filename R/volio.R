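## Volumetric image container and I/O.
##
## Volumes are kept deliberately simple: a 3D numeric array of intensities,
## an isotropic voxel size in mm, and a world-space origin (mm position of
## the center of voxel [1,1,1]). NIfTI-1 I/O goes through RNifti and
## Analyze 7.5 through oro.nifti; both round-trip float64 data bit-exactly.

#' Construct a voxel volume
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param voxel_size isotropic voxel edge length (mm).
#' @param origin 3-vector, mm position of the center of voxel `[1,1,1]`.
#' @param meta named list of free-form metadata carried along (e.g. smoothing
#'   kernel, noise level, generating seed).
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size, origin = c(0, 0, 0), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("data must be a 3D array")
  if (any(dim(data) < 1)) stop("volume grid is empty")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a single positive number (mm)")
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin), meta = meta),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_volume: %d x %d x %d voxels @ %.4f mm (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# world-space mm coordinates of voxel centers along each grid axis
voxel_axes <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(i) vol$origin[i] + (seq_len(d[i]) - 1) * vol$voxel_size)
}

#' Read a volumetric image (NIfTI-1 or Analyze 7.5)
#'
#' @param path file path: `.nii` / `.nii.gz` for NIfTI-1, `.hdr` or `.img`
#'   for an Analyze 7.5 pair.
#' @return a [voxel_volume()].
#' @details Anisotropic voxels are rejected: every pipeline stage assumes
#'   isotropic sampling. Voxel sizes are taken from the header `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path) && !grepl("\\.(hdr|img)$", path))
    stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    px <- RNifti::pixdim(img)[1:3]
    arr <- as.array(img)
    if (length(dim(arr)) == 4 && dim(arr)[4] == 1) dim(arr) <- dim(arr)[1:3]
  } else if (grepl("\\.(hdr|img)(\\.gz)?$", path)) {
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    gz <- grepl("\\.gz$", path)
    ext <- if (gz) c(".hdr.gz", ".img.gz") else c(".hdr", ".img")
    missing <- ext[!file.exists(paste0(stem, ext))]
    if (length(missing))
      stop("incomplete Analyze pair: missing ", paste0(stem, missing, collapse = ", "))
    img <- oro.nifti::readANALYZE(stem)
    px <- img@pixdim[2:4]
    arr <- img@.Data
    dn <- dim(arr)
    if (length(dn) == 4 && dn[4] == 1) dim(arr) <- dn[1:3]
  } else {
    stop("unsupported volume format: ", path,
         " (expected .nii, .nii.gz, .hdr or .img)")
  }
  if (length(dim(arr)) != 3) stop("volume is not 3-dimensional: ", path)
  px <- abs(px)
  if (any(px <= 0)) stop("malformed header: non-positive pixdim in ", path)
  if (diff(range(px)) > 1e-6 * mean(px))
    stop(sprintf("anisotropic voxels (%.6g x %.6g x %.6g mm) are not supported",
                 px[1], px[2], px[3]))
  voxel_volume(unclass(arr), voxel_size = mean(px))
}

#' Write a volumetric image (NIfTI-1 or Analyze 7.5)
#'
#' @param vol a [voxel_volume()].
#' @param path destination: `.nii` / `.nii.gz` or `.hdr` / `.img`.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  vs <- vol$voxel_size
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- c(vs, vs, vs)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.(hdr|img)$", path)) {
    stem <- sub("\\.(hdr|img)$", "", path)
    img <- oro.nifti::anlz(vol$data, datatype = 64L, bitpix = 64L)
    img@pixdim <- c(length(dim(vol$data)), vs, vs, vs, rep(0, 4))
    oro.nifti::writeANALYZE(img, stem, gzipped = FALSE)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' Gaussian pre-smoothing of a volume
#'
#' Separable Gaussian filter in world units. The kernel size is the Gaussian
#' standard deviation in mm by default; pass `kernel_is_fwhm = TRUE` to
#' interpret it as full width at half maximum instead.
#'
#' @param vol a [voxel_volume()].
#' @param kernel_mm kernel size in mm (default 0.1); 0 returns the input
#'   unchanged.
#' @param kernel_is_fwhm interpret `kernel_mm` as FWHM rather than sigma.
#' @return the smoothed [voxel_volume()]; the kernel used is recorded in
#'   `meta$smoothing`.
#' @details Edge handling renormalizes the truncated kernel so that constant
#'   volumes are exactly preserved and the mean intensity is conserved up to
#'   edge truncation.
#' @export
gaussian_smooth <- function(vol, kernel_mm = 0.1, kernel_is_fwhm = FALSE) {
  stopifnot(inherits(vol, "voxel_volume"), kernel_mm >= 0)
  if (kernel_mm == 0) return(vol)
  sigma_mm <- if (kernel_is_fwhm) kernel_mm / (2 * sqrt(2 * log(2))) else kernel_mm
  sigma_vox <- sigma_mm / vol$voxel_size
  out <- vol
  out$data <- smooth_array(vol$data, sigma_vox)
  out$meta$smoothing <- list(kernel_mm = kernel_mm, sigma_mm = sigma_mm,
                             kernel_is_fwhm = kernel_is_fwhm)
  out
}

# Separable Gaussian smoothing of a raw 3D array, sigma in voxels.
# Band-sparse convolution matrix per axis, rows renormalized at the edges.
smooth_array <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  for (ax in 1:3) arr <- convolve_axis(arr, k, ax)
  arr
}

convolve_axis <- function(arr, k, ax) {
  d <- dim(arr)
  n <- d[ax]
  r <- (length(k) - 1L) / 2L
  blocks <- lapply(seq_len(n), function(i) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= n
    w <- k[keep]
    cbind(i = rep(i, sum(keep)), j = j[keep], x = w / sum(w))
  })
  trip <- do.call(rbind, blocks)
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(n, n))
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- matrix(a, nrow = n)
  m <- as.matrix(S %*% m)
  a <- array(m, dp)
  aperm(a, order(perm))
}

#' Crop individual eyes out of a 2x2x4 array scan
#'
#' Splits a 16-eye array volume into one sub-volume per eye, either from the
#' known layout manifest (as produced by [assemble_array()]) or by automatic
#' detection: global Otsu thresholding, 26-connected labeling of the bright
#' globe interiors, clustering of the component centroids onto the 2x2x4
#' grid, and orientation of each eye from the offset of its bright lens from
#' the globe centroid. The single inverted eye anchors the identity
#' assignment: in-plane rotations (and an upside-down flip) of the array are
#' undone so that the inverted eye lands in the reference cell.
#'
#' @param vol array-scan [voxel_volume()].
#' @param layout optional layout manifest from [assemble_array()]; `NULL`
#'   requests automatic detection.
#' @param margin_mm margin added around each globe bounding box (mm).
#' @param min_component_voxels components smaller than this are ignored as
#'   noise during automatic detection.
#' @return a list with `eyes` (list of 16 cropped [voxel_volume()]s, in eye-id
#'   order) and `manifest` (data frame: eye id, grid cell, bounding box in
#'   0-based half-open voxel coordinates, orientation).
#' @export
crop_eyes <- function(vol, layout = NULL, margin_mm = 1,
                      min_component_voxels = 200) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  if (!is.null(layout)) {
    cells <- layout$cells
    eyes <- lapply(seq_len(nrow(cells)), function(r) {
      crop_box(vol, c(cells$x0[r], cells$y0[r], cells$z0[r]),
               c(cells$x1[r], cells$y1[r], cells$z1[r]))
    })
    ord <- order(cells$eye_id)
    return(list(eyes = eyes[ord], manifest = cells[ord, , drop = FALSE]))
  }
  thr <- otsu_threshold(as.numeric(vol$data))
  bright <- vol$data > thr
  lab <- .label_cc(bright, 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_component_voxels)
  if (length(keep) != 16)
    stop(sprintf("expected 16 globes, detected %d", length(keep)))
  # per-component centroids, bounding boxes, orientation
  info <- lapply(keep, function(id) {
    idx <- which(lab == id)
    co <- arrayInd(idx, d)
    vals <- vol$data[idx]
    # the lens is the bright phase within the globe interior (humor + lens)
    lens_thr <- otsu_threshold(vals)
    lens_sel <- if (is.na(lens_thr)) vals >= quantile(vals, 0.98)
                else vals > lens_thr
    if (!any(lens_sel)) lens_sel <- vals >= quantile(vals, 0.98)
    list(centroid = colMeans(co),
         lens_dz = mean(co[lens_sel, 3]) - mean(co[, 3]),
         box0 = apply(co, 2, min), box1 = apply(co, 2, max))
  })
  cen <- t(vapply(info, `[[`, numeric(3), "centroid"))
  # cluster onto the 2x2x4 grid
  kz <- cut(rank(cen[, 3], ties.method = "first"), breaks = 4, labels = FALSE)
  ii <- ifelse(cen[, 1] <= median(cen[, 1]), 1L, 2L)
  jj <- ifelse(cen[, 2] <= median(cen[, 2]), 1L, 2L)
  # orientation: anterior direction of each eye along +z or -z
  dz <- vapply(info, `[[`, numeric(1), "lens_dz")
  up <- dz > 0
  inverted <- if (sum(up) == 1) up else !up
  if (sum(inverted) != 1)
    stop(sprintf("could not identify a unique inverted eye (%d candidates)",
                 sum(inverted)))
  inv <- which(inverted)
  # undo array rotation: the inverted eye belongs in cell (2,2) of layer 4
  maps <- list(
    function(i, j) cbind(i, j),
    function(i, j) cbind(j, 3L - i),
    function(i, j) cbind(3L - i, 3L - j),
    function(i, j) cbind(3L - j, i))
  placed <- FALSE
  for (flip in c(FALSE, TRUE)) {
    kz2 <- if (flip) 5L - kz else kz
    for (m in maps) {
      ij <- m(ii, jj)
      if (kz2[inv] == 4L && ij[inv, 1] == 2L && ij[inv, 2] == 2L) {
        placed <- TRUE; break
      }
    }
    if (placed) break
  }
  if (!placed)
    stop("inverted eye position inconsistent with a rigid array rotation")
  ids <- (kz2 - 1L) * 4L + (ij[, 2] - 1L) * 2L + ij[, 1]
  if (anyDuplicated(ids)) stop("grid-cell assignment is not one-to-one")
  mar <- ceiling(margin_mm / vol$voxel_size)
  manifest <- data.frame(
    eye_id = ids, cell_i = ij[, 1], cell_j = ij[, 2], cell_k = kz2,
    x0 = pmax(vapply(info, function(x) x$box0[1], 0) - mar, 1) - 1,
    y0 = pmax(vapply(info, function(x) x$box0[2], 0) - mar, 1) - 1,
    z0 = pmax(vapply(info, function(x) x$box0[3], 0) - mar, 1) - 1,
    x1 = pmin(vapply(info, function(x) x$box1[1], 0) + mar, d[1]),
    y1 = pmin(vapply(info, function(x) x$box1[2], 0) + mar, d[2]),
    z1 = pmin(vapply(info, function(x) x$box1[3], 0) + mar, d[3]),
    orientation = ifelse(inverted, "inverted", "normal"))
  ord <- order(manifest$eye_id)
  manifest <- manifest[ord, , drop = FALSE]
  eyes <- lapply(seq_len(nrow(manifest)), function(r) {
    crop_box(vol, c(manifest$x0[r], manifest$y0[r], manifest$z0[r]),
             c(manifest$x1[r], manifest$y1[r], manifest$z1[r]))
  })
  list(eyes = eyes, manifest = manifest)
}

# crop [b0, b1) in 0-based half-open voxel coordinates
crop_box <- function(vol, b0, b1) {
  i <- (b0[1] + 1):b1[1]; j <- (b0[2] + 1):b1[2]; k <- (b0[3] + 1):b1[3]
  voxel_volume(vol$data[i, j, k, drop = FALSE], vol$voxel_size,
               origin = vol$origin + b0 * vol$voxel_size,
               meta = vol$meta)
}
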
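## Shrink-wrap surface meshing. The template is an octahedron subdivided k
## times and projected to the unit sphere (8 * 4^k faces); wrapping casts a
## ray from the mask centroid through each template vertex and places the
## vertex at the outermost sub-voxel 0.5-occupancy crossing of the softened
## (1-voxel Gaussian) binary mask. Vertex smoothing is Taubin's
## shrink-free lambda/mu two-step by default.

#' Initialize the unit template mesh
#'
#' An octahedron subdivided until the face budget is reached, with all
#' vertices projected to the unit sphere. Budgets must be `8 * 4^k`; the
#' default `32768` (k = 6) gives 16,386 vertices and 49,152 edges.
#'
#' @param face_budget requested number of triangles, `8 * 4^k`.
#' @return an object of class `lens_mesh`: `vertices` (V x 3), `faces`
#'   (F x 3, consistently outward-oriented).
#' @export
init_mesh <- function(face_budget = 32768) {
  k <- log(face_budget / 8, base = 4)
  if (face_budget < 8 || abs(k - round(k)) > 1e-9) {
    adm <- 8 * 4^(0:8)
    stop("face_budget must be 8 * 4^k; admissible values: ",
         paste(adm, collapse = ", "))
  }
  k <- as.integer(round(k))
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (i in seq_len(k)) {
    sub <- subdivide_mesh(v, f)
    v <- sub$vertices
    f <- sub$faces
    v <- v / sqrt(rowSums(v^2))
  }
  new_lens_mesh(v, f)
}

new_lens_mesh <- function(vertices, faces, anterior = NULL, centroid = NULL) {
  structure(list(vertices = vertices, faces = faces,
                 anterior = anterior, centroid = centroid),
            class = "lens_mesh")
}

#' @export
print.lens_mesh <- function(x, ...) {
  cat(sprintf("lens_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# one 1-to-4 loop subdivision step (midpoint insertion, no smoothing)
subdivide_mesh <- function(v, f) {
  nf <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- unique(key)
  mid_id <- match(key, uk) + nrow(v)
  ue <- e[!duplicated(key), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  v2 <- rbind(v, mids)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(m12, f[, 2], m23),
              cbind(m31, m23, f[, 3]),
              cbind(m12, m23, m31))
  list(vertices = v2, faces = f2)
}

#' Audit mesh topology
#'
#' Checks that the mesh is a closed, consistently oriented 2-manifold: every
#' undirected edge is shared by exactly two faces with opposite directions,
#' the Euler characteristic is 2, and no face has (near-)zero area.
#'
#' @param mesh a `lens_mesh`.
#' @param area_tol faces with area below `area_tol` times the mean face area
#'   count as degenerate.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
check_mesh <- function(mesh, area_tol = 1e-10) {
  v <- mesh$vertices; f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key)
  if (any(tab != 2)) stop("mesh is not closed: some edges are not shared by exactly 2 faces")
  dirkey <- paste(he[, 1], he[, 2])
  if (anyDuplicated(dirkey))
    stop("mesh orientation is inconsistent: a directed edge appears twice")
  nE <- length(tab)
  if (nrow(v) - nE + nrow(f) != 2)
    stop("Euler characteristic is not 2")
  a <- face_areas(mesh)
  if (any(a < area_tol * mean(a))) stop("mesh contains degenerate faces")
  invisible(TRUE)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Shrink-wrap the template mesh over a lens mask
#'
#' Radial wrap: the binary mask is softened with a 1-voxel Gaussian, and each
#' template vertex direction (from the mask centroid) is traced from outside
#' inward to its outermost 0.5-occupancy crossing, located to sub-voxel
#' precision by linear interpolation of the sampled profile. Assumes the mask
#' is star-shaped about its centroid; rays crossing the boundary more than
#' once are counted and reported.
#'
#' @param mask a `lens_mask` (ideally repaired, see [repair_mask()]).
#' @param mesh template from [init_mesh()]; defaults to the 32,768-face
#'   budget.
#' @param intensity optional [voxel_volume()] (the smoothed grayscale image
#'   the mask was segmented from). When given, each vertex is refined to the
#'   crossing of the intensity at `level` near the binary boundary: the
#'   partial-volume intensity profile localizes the surface well below the
#'   voxel quantization limit of the binary mask, which matters for the
#'   curvature fits.
#' @param level intensity crossing level (defaults to the mask's segmentation
#'   threshold).
#' @param levels optional length-2 vector `c(inside, outside)` of global
#'   class plateau intensities (e.g. the `class_levels` attribute of
#'   [select_threshold()]); when given, occupancy profiles are normalized
#'   against these instead of per-ray plateau estimates, which removes the
#'   per-ray plateau noise from the refined surface.
#' @param soften_sigma_vox Gaussian sigma (voxels) used to soften the binary
#'   mask before interpolation.
#' @param step_vox radial sampling step (voxels).
#' @param multi_crossing_warn warn when more than this fraction of rays cross
#'   the boundary multiply.
#' @return a `lens_mesh` in mm coordinates, centroid recorded.
#' @export
shrink_wrap <- function(mask, mesh = init_mesh(), intensity = NULL,
                        level = NULL, levels = NULL, soften_sigma_vox = 1,
                        step_vox = 0.4, multi_crossing_warn = 0.01) {
  stopifnot(inherits(mask, "lens_mask"), inherits(mesh, "lens_mesh"))
  m <- mask$mask
  if (!any(m)) stop("cannot wrap an empty mask")
  vs <- mask$voxel_size
  soft <- smooth_array(array(as.numeric(m), dim(m)), soften_sigma_vox)
  idx <- which(m)
  co <- arrayInd(idx, dim(m))
  ctr_vox <- colMeans(co)                       # centroid, voxel coords
  dirs <- mesh$vertices
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # radial sampling out to the largest possible in-mask radius
  r_max <- (max(sweep(co, 2, ctr_vox)^2 |> rowSums() |> sqrt()) + 3)
  radii <- seq(0, r_max, by = step_vox)
  nv <- nrow(dirs); nr <- length(radii)
  vals <- matrix(0, nv, nr)
  for (j in seq_len(nr)) {
    pts <- sweep(dirs * radii[j], 2, ctr_vox, `+`)
    vals[, j] <- trilinear(soft, pts, outside = 0)
  }
  above <- vals >= 0.5
  if (any(!above[, 1])) {
    # centroid outside the soft mask would break the radial parameterization
    if (soft[round(ctr_vox[1]), round(ctr_vox[2]), round(ctr_vox[3])] < 0.5)
      warning("mask centroid is not inside the mask; wrap may be unreliable")
  }
  transitions <- rowSums(abs(above[, -1, drop = FALSE] -
                               above[, -nr, drop = FALSE]))
  multi <- mean(transitions > 1)
  if (multi > multi_crossing_warn)
    warning(sprintf(
      "%.1f%% of rays cross the boundary more than once (non-star-shaped mask)",
      100 * multi))
  # outermost crossing: largest sample index still >= 0.5
  last_in <- apply(above, 1, function(a) {
    w <- which(a)
    if (!length(w)) 1L else max(w)
  })
  last_in <- pmin(last_in, nr - 1L)
  i1 <- cbind(seq_len(nv), last_in)
  i2 <- cbind(seq_len(nv), last_in + 1L)
  v1 <- vals[i1]; v2 <- vals[i2]
  frac <- ifelse(v1 > v2, (v1 - 0.5) / (v1 - v2), 0)
  r_cross <- radii[last_in] + frac * step_vox
  verts_vox <- sweep(dirs * r_cross, 2, ctr_vox, `+`)
  if (!is.null(intensity)) {
    stopifnot(inherits(intensity, "voxel_volume"))
    if (!isTRUE(all.equal(dim(intensity$data), dim(m))))
      stop("intensity volume and mask grids differ")
    level <- level %||% mask$threshold
    levels <- levels %||% attr(mask$threshold, "class_levels")
    # first sub-voxel pass along the rays, then a pass along the vertex
    # normals: integrating the partial-volume profile obliquely to the
    # surface acquires an obliquity-dependent bias, and the centroid rays
    # are oblique everywhere except at the poles
    r_cross <- refine_crossing_intensity(intensity$data, ctr_vox, dirs,
                                         r_cross, level, levels = levels)
    verts_vox <- sweep(dirs * r_cross, 2, ctr_vox, `+`)
    nrm <- vertex_normals(new_lens_mesh(verts_vox, mesh$faces))
    off <- refine_offsets(intensity$data, verts_vox, nrm, level,
                          levels = levels)
    verts_vox <- verts_vox + nrm * off
  }
  verts_mm <- sweep((verts_vox - 1) * vs, 2, mask$origin, `+`)
  ctr_mm <- mask$origin + (ctr_vox - 1) * vs
  new_lens_mesh(verts_mm, mesh$faces, centroid = ctr_mm)
}

# Refine per-ray boundary radii against the grayscale volume by partial-
# volume integration: within a window around the coarse (binary-mask)
# radius, normalize the intensity profile to an occupancy in [0, 1] using
# per-ray inside/outside plateau levels and place the surface so that the
# integrated occupancy is conserved. Unlike a level crossing on the
# trilinearly interpolated profile, this is unbiased irrespective of the
# voxel phase (level crossings acquire a coherent sub-voxel bias wherever
# the surface runs parallel to a voxel layer, which is exactly the pole
# region the curvature fits depend on). Rays whose window does not show a
# clean bright-to-dark transition through `level` keep the coarse radius.
refine_crossing_intensity <- function(arr, ctr_vox, dirs, r0, level,
                                      window_vox = 3.5, step_vox = 0.1,
                                      passes = 2, levels = NULL) {
  base <- sweep(dirs * r0, 2, ctr_vox, `+`)
  off <- refine_offsets(arr, base, dirs, level, window_vox, step_vox, passes,
                        levels = levels)
  r0 + off
}

# Signed offsets along `dirs` (unit, pointing inside -> outside) moving each
# base point onto the interface, by partial-volume integration of the
# intensity within a window around the point. The window must cover the full
# smoothed transition plus plateau bands on both sides, and is recentered
# between passes so that asymmetric tail truncation vanishes. Points without
# a clean bright-to-dark transition through `level` keep offset 0.
refine_offsets <- function(arr, base, dirs, level, window_vox = 3.5,
                           step_vox = 0.1, passes = 2, levels = NULL) {
  offs <- seq(-window_vox, window_vox, by = step_vox)
  no <- length(offs)
  plateau_in <- offs <= -window_vox + 0.7
  plateau_out <- offs >= window_vox - 0.7
  nv <- nrow(base)
  out <- numeric(nv)
  for (p in seq_len(passes)) {
    vals <- matrix(0, nv, no)
    for (j in seq_len(no)) {
      vals[, j] <- trilinear(arr, base + dirs * (out + offs[j]), outside = NA)
    }
    if (is.null(levels)) {
      I_in <- rowMeans(vals[, plateau_in, drop = FALSE])
      I_out <- rowMeans(vals[, plateau_out, drop = FALSE])
    } else {
      I_in <- rep(levels[[1]], nv)
      I_out <- rep(levels[[2]], nv)
    }
    ok <- !is.na(I_in) & !is.na(I_out) & I_in > level & I_out < level &
      rowSums(is.na(vals)) == 0
    if (!any(ok)) return(out)
    occ <- (vals[ok, , drop = FALSE] - I_out[ok]) / (I_in[ok] - I_out[ok])
    occ[occ < 0] <- 0
    occ[occ > 1] <- 1
    # trapezoid integral of occupancy: the interface sits where the
    # integrated occupancy equals the distance from the window start
    integ <- step_vox * (rowSums(occ) - (occ[, 1] + occ[, no]) / 2)
    out[ok] <- out[ok] - window_vox + integ
  }
  out
}

# area-weighted outward vertex normals
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (c0 in 1:3) {
      acc <- rowsum(fn[, c0], f[, k], reorder = FALSE)
      n[as.integer(rownames(acc)), c0] <- n[as.integer(rownames(acc)), c0] +
        acc[, 1]
    }
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-12)
}

# row-normalized vertex adjacency operator (sparse)
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / deg) %*% A
}

#' Smooth mesh vertices
#'
#' Removes the surface undulations inherent to the wrapped polygonal mesh.
#' Default is Taubin's volume-preserving lambda/mu two-step; plain Laplacian
#' smoothing (which shrinks the mesh) is available via `method`.
#'
#' @param mesh a `lens_mesh`.
#' @param iterations number of smoothing passes (default 10); 0 returns the
#'   input unchanged.
#' @param lambda positive smoothing factor in (0, 1].
#' @param mu negative counter-smoothing factor of the Taubin step.
#' @param method `"taubin"` or `"laplacian"`.
#' @return the smoothed `lens_mesh`.
#' @export
smooth_vertices <- function(mesh, iterations = 10, lambda = 0.33, mu = -0.34,
                            method = c("taubin", "laplacian")) {
  stopifnot(inherits(mesh, "lens_mesh"), iterations >= 0,
            lambda > 0, lambda <= 1)
  method <- match.arg(method)
  if (iterations == 0) return(mesh)
  W <- vertex_adjacency(mesh)
  v <- mesh$vertices
  for (i in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(W %*% v) - v)
    if (method == "taubin")
      v <- v + mu * (as.matrix(W %*% v) - v)
  }
  out <- mesh
  out$vertices <- v
  out
}

#' RMS vertex Laplacian norm (surface roughness)
#'
#' @param mesh a `lens_mesh`.
#' @return root-mean-square length of the umbrella Laplacian over vertices.
#' @export
mesh_roughness <- function(mesh) {
  W <- vertex_adjacency(mesh)
  L <- as.matrix(W %*% mesh$vertices) - mesh$vertices
  sqrt(mean(rowSums(L^2)))
}

#' Export a mesh as PLY (ASCII) or OBJ
#'
#' @param mesh a `lens_mesh`.
#' @param path destination path ending in `.ply` or `.obj`.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "lens_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (grepl("\\.ply$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(v, 1, paste, collapse = " "), con)
    writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  } else if (grepl("\\.obj$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    stop("unsupported mesh format: ", path)
  }
  invisible(path)
}
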
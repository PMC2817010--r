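## Lens biometry from a fitted surface mesh: optical-axis definition, axial
## thickness, equatorial diameter, divergence-theorem volume, surface
## radii of curvature by an axis-constrained Powell sphere fit over a 60
## degree cap, and the objective kidney-shape classifier.

#' Define the approximate optical axis of a lens mesh
#'
#' The axis runs from the area-weighted surface centroid of the mesh to a
#' point marking the center of the anterior surface. If no anterior point is
#' supplied, the lens' short principal axis is used (oriented by
#' `orient_hint`) and the anterior point is the surface vertex farthest along
#' it.
#'
#' @param mesh a `lens_mesh`.
#' @param anterior_point 3-vector on (or near) the anterior surface, or
#'   `NULL` for automatic selection.
#' @param orient_hint direction whose sign disambiguates anterior from
#'   posterior in automatic mode (default +z, this package's phantom and
#'   array convention).
#' @param max_surface_dist_mm maximum allowed distance of `anterior_point`
#'   from the mesh surface (default 0.25 mm, about two voxels at scanning
#'   resolution).
#' @return a list with unit `dir` (anterior direction), `point` (the
#'   centroid) and `anterior` (the anterior surface point used).
#' @export
define_axis <- function(mesh, anterior_point = NULL,
                        orient_hint = c(0, 0, 1),
                        max_surface_dist_mm = 0.25) {
  stopifnot(inherits(mesh, "lens_mesh"))
  ctr <- mesh_surface_centroid(mesh)
  v <- mesh$vertices
  if (is.null(anterior_point)) {
    cv <- sweep(v, 2, colMeans(v))
    ev <- eigen(crossprod(cv) / nrow(cv), symmetric = TRUE)
    ax <- ev$vectors[, 3]   # smallest spread = lens axial direction
    if (sum(ax * orient_hint) < 0) ax <- -ax
    # anchor the anterior point where the principal axis meets the surface
    # (the farthest vertex would sit on the rim of a kidney depression and
    # tilt the axis)
    ts <- ray_mesh_t(mesh, ctr, ax)
    ts <- ts[ts > 0]
    if (!length(ts)) stop("principal axis does not intersect the mesh")
    anterior_point <- ctr + ax * max(ts)
  } else {
    anterior_point <- as.numeric(anterior_point)
    dmin <- sqrt(min(rowSums(sweep(v, 2, anterior_point)^2)))
    if (dmin > max_surface_dist_mm)
      stop(sprintf("anterior point is %.3f mm from the mesh surface (max %.3f)",
                   dmin, max_surface_dist_mm))
  }
  dir <- unitize(anterior_point - ctr)
  list(dir = dir, point = ctr, anterior = anterior_point)
}

# area-weighted centroid of the triangulated surface
mesh_surface_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  a <- face_areas(mesh)
  colSums(fc * a) / sum(a)
}

# all intersection parameters t of the line point + t*dir with the mesh
# (Moller-Trumbore, vectorized over faces; duplicate hits on shared edges
# are merged)
ray_mesh_t <- function(mesh, point, dir) {
  v <- mesh$vertices; f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p0
  e2 <- v[f[, 3], , drop = FALSE] - p0
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  s <- sweep(p0, 2, point, `-`) * -1
  u <- rowSums(s * h) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / det
  tt <- rowSums(e2 * q) / det
  eps <- 1e-9
  hit <- ok & u >= -eps & vv >= -eps & (u + vv) <= 1 + eps
  ts <- sort(tt[hit])
  if (!length(ts)) return(numeric(0))
  # merge duplicates from edge/vertex hits
  keep <- c(TRUE, diff(ts) > 1e-6)
  ts[keep]
}

#' Axial lens thickness
#'
#' Distance between the two intersections of the optical axis with the mesh
#' surface (anterior pole to posterior pole).
#'
#' @param mesh a `lens_mesh`.
#' @param axis axis from [define_axis()].
#' @return thickness in mm.
#' @export
axial_thickness <- function(mesh, axis) {
  ts <- ray_mesh_t(mesh, axis$point, axis$dir)
  if (length(ts) != 2)
    stop(sprintf("axis intersects the mesh in %d points (expected 2)",
                 length(ts)))
  diff(ts)
}

#' Equatorial lens diameter
#'
#' Maximum caliper width of the mesh projected onto the plane orthogonal to
#' the optical axis: the largest pairwise distance between projected hull
#' vertices, which is the maximum in-plane extent over all directions.
#'
#' @param mesh a `lens_mesh`.
#' @param axis axis from [define_axis()].
#' @return diameter in mm.
#' @export
equatorial_diameter <- function(mesh, axis) {
  B <- orthobasis(axis$dir)
  p <- mesh$vertices %*% t(B)
  h <- chull(p)
  ph <- p[h, , drop = FALSE]
  d2 <- as.matrix(dist(ph))
  max(d2)
}

#' Mesh volume via the divergence theorem
#'
#' Sum of signed tetrahedra from the vertex centroid to each face. Positive
#' for outward-oriented meshes; an inward orientation is detected, corrected
#' and reported with a warning.
#'
#' @param mesh a `lens_mesh` (must be closed; checked).
#' @param check audit closedness/orientation first (default TRUE).
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  if (check) check_mesh(mesh)
  v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  vol6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- sum(vol6) / 6
  if (vol < 0) {
    warning("mesh is inward-oriented; sign corrected")
    vol <- -vol
  }
  vol
}

#' Fit a sphere to one lens surface over a 60 degree cap
#'
#' Selects the mesh vertices inside a cone about the optical axis (apex at
#' the surface centroid, on the anterior or posterior side) and fits a
#' sphere minimizing \eqn{\sum_i (\|v_i - c\| - r)^2}, with the center
#' constrained to the axis line by default. The minimization uses Powell's
#' direction-set method started from an algebraic (Kasa) fit.
#'
#' @param mesh a `lens_mesh`.
#' @param axis axis from [define_axis()].
#' @param surface `"anterior"` or `"posterior"`.
#' @param cone_full_angle full apex angle of the selection cone in degrees.
#'   The default 120 takes "subtending 60 degrees to the axis" as the
#'   half-angle (vertices within 60 degrees of the axis); pass 60 for the
#'   narrow full-apex-angle reading. At scanning resolution the narrow patch
#'   offers too little lateral lever arm for a stable curvature estimate.
#' @param free_center fit an unconstrained 3D center instead of one on the
#'   axis line.
#' @param min_vertices minimum cone population (default 50).
#' @return an object of class `sphere_fit`: `center` (mm), `radius` (mm),
#'   `rms` residual (mm), `cone_half_angle_deg`, `n` vertices used,
#'   `converged`.
#' @export
fit_surface_sphere <- function(mesh, axis, surface = c("anterior", "posterior"),
                               cone_full_angle = 120, free_center = FALSE,
                               min_vertices = 50) {
  surface <- match.arg(surface)
  half <- cone_full_angle / 2
  u <- if (surface == "anterior") axis$dir else -axis$dir
  sel <- cone_vertices(mesh, axis$point, u, 0, half)
  if (nrow(sel) < min_vertices)
    stop(sprintf("only %d vertices in the %s %g-degree cone (need >= %d)",
                 nrow(sel), surface, cone_full_angle, min_vertices))
  fit <- sphere_fit_points(sel, axis, u, free_center)
  fit$cone_half_angle_deg <- half
  fit$surface <- surface
  fit
}

# vertices whose direction from `apex` is within [lo, hi] degrees of unit u
cone_vertices <- function(mesh, apex, u, lo, hi) {
  w <- sweep(mesh$vertices, 2, apex)
  wn <- sqrt(rowSums(w^2))
  cosang <- as.numeric(w %*% u) / pmax(wn, 1e-12)
  cosang <- pmin(pmax(cosang, -1), 1)
  ang <- acos(cosang) * 180 / pi
  mesh$vertices[ang >= lo & ang <= hi & wn > 1e-9, , drop = FALSE]
}

sphere_fit_points <- function(pts, axis, u, free_center = FALSE,
                              ptol = 1e-6) {
  obj_dist <- function(ctr) {
    d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    r <- mean(d)
    sum((d - r)^2)
  }
  # initialization: the center must lie behind the surface patch along u;
  # a shallow noisy patch makes the algebraic (Kasa) fit collapse, so scan
  # the center position coarsely before refining with Powell
  m <- mean(as.numeric(sweep(pts, 2, axis$point) %*% u))
  t_grid <- m - exp(seq(log(0.05), log(60), length.out = 120))
  f_grid <- vapply(t_grid, function(t) obj_dist(axis$point + t * u), 0)
  t0 <- t_grid[which.min(f_grid)]
  if (free_center) {
    c0 <- axis$point + t0 * u
    res <- powell(obj_dist, c0, step = 0.2, ptol = ptol)
    ctr <- res$par
  } else {
    # center constrained to the axis line: parameters (t, r) with r profiled
    objt <- function(p) obj_dist(axis$point + p[1] * u)
    res <- powell(objt, t0, step = 0.2, ptol = ptol)
    ctr <- axis$point + res$par[1] * u
  }
  if (!res$converged)
    stop(sprintf("sphere fit did not converge (last residual %.3e)", res$value))
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  r <- mean(d)
  structure(list(center = ctr, radius = r,
                 rms = sqrt(mean((d - r)^2)), n = nrow(pts),
                 objective = res$value, converged = res$converged,
                 free_center = free_center),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit (%s): r = %.3f mm, rms = %.4f mm, n = %d\n",
              x$surface %||% "?", x$radius, x$rms, x$n))
  invisible(x)
}

#' Objective kidney-shape classification
#'
#' Measures the depth of a central anterior-surface depression as the maximum
#' inward deviation of near-axis vertices from a reference sphere fitted to
#' the surrounding (un-dented) anterior annulus, and classifies the lens as
#' kidney-shaped when the depth exceeds a threshold.
#'
#' @param mesh a `lens_mesh`.
#' @param axis axis from [define_axis()].
#' @param fit optional anterior [fit_surface_sphere()] result, carried along
#'   in the output for reporting; the depth itself is measured against the
#'   annulus reference so that the dent cannot drag its own reference down.
#' @param threshold_mm depression depth above which the lens is called
#'   kidney-shaped (default 0.15 mm, about 1.3 voxels at scanning
#'   resolution).
#' @param depth_cone_deg vertices within this angle of the axis are scanned
#'   for the depression (default 15 degrees).
#' @param annulus_deg angular band (degrees from the axis) of anterior
#'   vertices from which the reference sphere is fitted.
#' @param exclude_tol_mm robust-reference tolerance: vertices deviating
#'   inward from the current reference by more than
#'   `max(exclude_tol_mm, 2.5 * mad)` are treated as dented and excluded
#'   before refitting. A depression's smooth shoulder extends well beyond
#'   its visually obvious core; fitting the reference through the shoulder
#'   tilts it and the tilt extrapolates to a large error at the pole, so the
#'   reference must be anchored on surface that is actually clean.
#' @param robust_iterations refit rounds (default 3).
#' @return list with `kidney` (logical), `depth` (mm), `reference_fit`, and
#'   the anterior `fit` passed in (possibly NULL).
#' @export
classify_kidney <- function(mesh, axis, fit = NULL, threshold_mm = 0.15,
                            depth_cone_deg = 15, annulus_deg = c(50, 75),
                            exclude_tol_mm = 0.02, robust_iterations = 3) {
  u <- axis$dir
  ref_pts <- cone_vertices(mesh, axis$point, u, annulus_deg[1], annulus_deg[2])
  if (nrow(ref_pts) < 50)
    stop("too few anterior annulus vertices for the reference sphere")
  keep <- rep(TRUE, nrow(ref_pts))
  ref <- NULL
  for (it in seq_len(robust_iterations)) {
    ref <- sphere_fit_points(ref_pts[keep, , drop = FALSE], axis, u,
                             free_center = FALSE)
    dev <- ref$radius - sqrt(rowSums(sweep(ref_pts, 2, ref$center)^2))
    tol <- max(exclude_tol_mm, 2.5 * mad(dev[keep]))
    keep_new <- dev < tol
    if (sum(keep_new) < 100) break
    if (identical(keep_new, keep)) break
    keep <- keep_new
  }
  core <- cone_vertices(mesh, axis$point, u, 0, depth_cone_deg)
  if (nrow(core) < 3) stop("too few near-axis anterior vertices")
  dev_in <- ref$radius - sqrt(rowSums(sweep(core, 2, ref$center)^2))
  depth <- max(dev_in)
  list(kidney = depth > threshold_mm, depth = depth,
       reference_fit = ref, fit = fit, threshold_mm = threshold_mm)
}

#' Full biometry of one lens mesh
#'
#' Runs the complete measurement set: axis definition, axial thickness,
#' equatorial diameter, mesh volume, anterior/posterior sphere fits and the
#' kidney classifier.
#'
#' @param mesh a `lens_mesh`.
#' @param anterior_point,orient_hint see [define_axis()].
#' @param mask optional `lens_mask`; when given, the voxel-count volume is
#'   reported alongside the mesh volume.
#' @param cone_full_angle,free_center see [fit_surface_sphere()].
#' @param kidney_threshold_mm see [classify_kidney()].
#' @return an object of class `lens_biometry` (also a one-row data frame via
#'   [as.data.frame()]): thickness, equatorial diameter, volumes, radii,
#'   kidney flag and depression depth, fit RMS values.
#' @export
measure_lens <- function(mesh, anterior_point = NULL, orient_hint = c(0, 0, 1),
                         mask = NULL, cone_full_angle = 120,
                         free_center = FALSE, kidney_threshold_mm = 0.15) {
  axis <- define_axis(mesh, anterior_point, orient_hint)
  fit_a <- fit_surface_sphere(mesh, axis, "anterior", cone_full_angle,
                              free_center)
  fit_p <- fit_surface_sphere(mesh, axis, "posterior", cone_full_angle,
                              free_center)
  kid <- classify_kidney(mesh, axis, fit_a, kidney_threshold_mm)
  out <- list(
    thickness_mm = axial_thickness(mesh, axis),
    eq_diam_mm = equatorial_diameter(mesh, axis),
    volume_mm3 = mesh_volume(mesh),
    voxel_volume_mm3 = if (!is.null(mask)) mask_volume(mask) else NA_real_,
    Ra_mm = fit_a$radius,
    Rp_mm = fit_p$radius,
    kidney = kid$kidney,
    depth_mm = kid$depth,
    fit_rms_a_mm = fit_a$rms,
    fit_rms_p_mm = fit_p$rms,
    axis = axis)
  class(out) <- "lens_biometry"
  out
}

#' @export
print.lens_biometry <- function(x, ...) {
  cat(sprintf(
    paste0("lens_biometry: T = %.3f mm, d_eq = %.3f mm, V = %.2f mm^3, ",
           "R_a = %.3f mm, R_p = %.3f mm, kidney = %s (depth %.3f mm)\n"),
    x$thickness_mm, x$eq_diam_mm, x$volume_mm3, x$Ra_mm, x$Rp_mm,
    x$kidney, x$depth_mm))
  invisible(x)
}

#' @export
as.data.frame.lens_biometry <- function(x, ...) {
  data.frame(thickness_mm = x$thickness_mm, eq_diam_mm = x$eq_diam_mm,
             volume_mm3 = x$volume_mm3,
             voxel_volume_mm3 = x$voxel_volume_mm3,
             Ra_mm = x$Ra_mm, Rp_mm = x$Rp_mm, kidney = x$kidney,
             depth_mm = x$depth_mm, fit_rms_a_mm = x$fit_rms_a_mm,
             fit_rms_p_mm = x$fit_rms_p_mm)
}
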
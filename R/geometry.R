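## Analytic two-cap lens geometry and the fixation-artifact deformation model.
##
## The lens is modelled as the union of two spherical caps (anterior radius
## R_a, posterior radius R_p) sharing a base circle of radius r_e in the
## equatorial plane. Cap heights h_a, h_p satisfy
##   h_a + h_p = T            (axial thickness)
##   r_e^2 = h_a (2 R_a - h_a) = h_p (2 R_p - h_p)   (shared base circle)
## which has the closed-form solution h_a = T (2 R_p - T) / (2 (R_a + R_p - T)).

#' Solve the biconvex two-cap lens geometry
#'
#' Given the anterior and posterior surface radii of curvature and the axial
#' thickness, returns the cap heights, the equatorial radius and the analytic
#' volume of the two-cap solid.
#'
#' @param R_a anterior surface radius of curvature (mm).
#' @param R_p posterior surface radius of curvature (mm).
#' @param T_ax axial thickness (mm), pole to pole.
#' @return a list with `h_a`, `h_p` (cap heights, mm), `r_e` (equatorial
#'   radius, mm) and `volume` (mm^3).
#' @details The volume is \eqn{V = \pi/3 [h_a^2 (3R_a - h_a) + h_p^2 (3R_p - h_p)]}.
#'   Geometries where the caps cannot close onto a common base circle raise a
#'   condition of class `lensmetry_geometry_error`.
#' @examples
#' solve_biconvex_geometry(3.0, 3.5, 2.4)
#' # degenerate full sphere: both caps are hemispheres of the same sphere
#' solve_biconvex_geometry(2, 2, 4)$volume  # 4/3 * pi * 2^3
#' @export
solve_biconvex_geometry <- function(R_a, R_p, T_ax) {
  stopifnot(is.numeric(R_a), is.numeric(R_p), is.numeric(T_ax))
  if (R_a <= 0 || R_p <= 0 || T_ax <= 0)
    geometry_error("R_a, R_p and T must all be positive")
  den <- 2 * (R_a + R_p - T_ax)
  num <- T_ax * (2 * R_p - T_ax)
  if (abs(den) < 1e-12 * max(R_a, R_p, T_ax)) {
    # limit R_a + R_p -> T: consistent only when the two caps are
    # complementary halves of one sphere (R_a = R_p = T/2)
    if (abs(num) < 1e-9 * T_ax^2) {
      h_a <- T_ax / 2
    } else {
      geometry_error("caps cannot close: R_a + R_p = T with R_a != R_p")
    }
  } else {
    h_a <- num / den
  }
  h_p <- T_ax - h_a
  if (!(h_a > 0 && h_p > 0))
    geometry_error(sprintf(
      "caps cannot close: solved anterior cap height %.4f outside (0, T)", h_a))
  if (h_a > 2 * R_a || h_p > 2 * R_p)
    geometry_error("caps cannot close: cap height exceeds sphere diameter")
  r2a <- h_a * (2 * R_a - h_a)
  r2p <- h_p * (2 * R_p - h_p)
  if (abs(r2a - r2p) > 1e-10)
    geometry_error(sprintf(
      "shared-base residual %.3e mm^2 exceeds tolerance", abs(r2a - r2p)))
  if (r2a <= 0) geometry_error("degenerate base circle (r_e^2 <= 0)")
  volume <- pi / 3 * (h_a^2 * (3 * R_a - h_a) + h_p^2 * (3 * R_p - h_p))
  list(h_a = h_a, h_p = h_p, r_e = sqrt(r2a), volume = volume)
}

geometry_error <- function(msg) {
  stop(structure(
    class = c("lensmetry_geometry_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Specify a (possibly deformed) crystalline lens phantom
#'
#' A `lens_spec` is the ground-truth description of one phantom lens: a
#' biconvex two-cap solid, optionally carrying the fixation artifact
#' (a Gaussian-in-angle posterior displacement of the anterior surface,
#' producing the characteristic "kidney" depression) and a global isotropic
#' shrink factor.
#'
#' @param R_a,R_p anterior / posterior radii of curvature (mm).
#' @param T_ax axial thickness of the undeformed lens (mm).
#' @param center 3-vector, position of the equatorial-plane center (mm).
#' @param axis unit 3-vector pointing in the anterior direction.
#' @param D depression depth of the kidney artifact (mm); 0 = biconvex.
#' @param sigma_theta angular width (radians, measured from the lens center)
#'   of the anterior depression.
#' @param shrink global isotropic scale factor in (0, 1]; 1 = no shrinkage.
#' @return an object of class `lens_spec` with the inputs plus the solved cap
#'   geometry (`h_a`, `h_p`, `r_e`, `volume`).
#' @details A warning is emitted when `D >= 0.8 * h_a * shrink`: beyond that
#'   bound the depression approaches the posterior cap and the surface is no
#'   longer a simple closed star-shaped boundary, which downstream mesh
#'   fitting assumes.
#' @export
lens_spec <- function(R_a, R_p, T_ax, center = c(0, 0, 0), axis = c(0, 0, 1),
                      D = 0, sigma_theta = 0.35, shrink = 1) {
  geom <- solve_biconvex_geometry(R_a, R_p, T_ax)
  stopifnot(length(center) == 3, length(axis) == 3,
            D >= 0, sigma_theta > 0, shrink > 0, shrink <= 1)
  axis <- unitize(axis)
  if (D >= 0.8 * geom$h_a * shrink)
    warning(sprintf(
      "depression depth D = %.3f mm >= 0.8 * h_a * s = %.3f mm: dent approaches the posterior cap",
      D, 0.8 * geom$h_a * shrink))
  structure(
    list(R_a = R_a, R_p = R_p, T_ax = T_ax, center = as.numeric(center),
         axis = axis, D = D, sigma_theta = sigma_theta, shrink = shrink,
         h_a = geom$h_a, h_p = geom$h_p, r_e = geom$r_e, volume = geom$volume),
    class = "lens_spec")
}

#' @export
print.lens_spec <- function(x, ...) {
  cat(sprintf(
    "lens_spec: R_a=%.3f R_p=%.3f T=%.3f mm (r_e=%.3f, V=%.2f mm^3), D=%.3f mm, s=%.3f\n",
    x$R_a, x$R_p, x$T_ax, x$r_e, x$volume, x$D, x$shrink))
  invisible(x)
}

#' Point-membership test for a deformed lens phantom
#'
#' Evaluates the implicit solid of a [lens_spec()] at arbitrary points: the
#' biconvex two-cap solid, with the anterior material displaced posteriorly
#' by \eqn{D \exp(-\theta^2 / (2\sigma_\theta^2))} (\eqn{\theta} = angle from
#' the anterior axis at the lens center) and the whole lens scaled by the
#' shrink factor about its center.
#'
#' @param spec a [lens_spec()].
#' @param pts n x 3 matrix of query points (mm).
#' @return logical vector of length n.
#' @export
lens_inside <- function(spec, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  q <- sweep(pts, 2, spec$center)
  if (spec$shrink < 1) q <- q / spec$shrink  # undo global shrink
  z <- as.numeric(q %*% spec$axis)
  rho2 <- pmax(rowSums(q^2) - z^2, 0)
  if (spec$D > 0) {
    theta <- atan2(sqrt(rho2), z)
    z <- z + spec$D * exp(-theta^2 / (2 * spec$sigma_theta^2))
  }
  c_a <- spec$h_a - spec$R_a   # anterior sphere center (axial coordinate)
  c_p <- spec$R_p - spec$h_p   # posterior sphere center
  (z >= 0 & rho2 + (z - c_a)^2 <= spec$R_a^2) |
    (z < 0 & rho2 + (z - c_p)^2 <= spec$R_p^2)
}

#' Pole-to-pole axial extent of a deformed lens phantom
#'
#' The exact extent of the implicit solid along its axis: the anterior pole is
#' displaced inward by the full depression depth `D`, the posterior pole by
#' the (normally negligible) tail of the angular Gaussian, and the result is
#' scaled by the shrink factor.
#'
#' @param spec a [lens_spec()].
#' @return axial extent (mm).
#' @export
lens_axial_extent <- function(spec) {
  w_post <- spec$D * exp(-pi^2 / (2 * spec$sigma_theta^2))
  spec$shrink * (spec$T_ax - spec$D + w_post)
}
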
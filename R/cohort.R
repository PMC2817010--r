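## Synthetic bird cohorts. Traits are drawn from a Gaussian copula with a
## target Spearman correlation matrix (latent Pearson correlation
## 2*sin(pi*rho/6)), lens geometry is solved per bird so that ground truth is
## exactly consistent with the two-cap model, and the fixation-shrinkage
## artifact is applied with a hatch-level random effect: most hatches carry
## little shrinkage, a minority carry strong shrinkage, so kidney prevalence
## clusters by hatch while scan groups (randomized scanning order) carry no
## effect.

cohort_trait_names <- c("volume", "eq_diam", "thickness", "axial_length",
                        "corneal_radius", "eye_weight", "eye_eq_diam",
                        "body_mass", "body_length")

#' Default Spearman correlation target for the cohort traits
#'
#' A two-factor loading structure: an overall size factor loading on every
#' trait, plus a lens-size factor loading on lens volume and thickness.
#' Lens volume ends up strongly tied to eye/body size and thickness weakly;
#' surface curvatures, which are derived from the residual volume-vs-shape
#' variation rather than sampled, stay essentially uncorrelated with body
#' size. The equatorial-diameter row is not free: cap geometry nearly
#' determines the diameter from volume and thickness, so its entries are
#' the self-consistent (model-implied) values measured from the generator
#' at large n -- most notably a negative diameter-thickness entry, because
#' at fixed volume a thicker two-cap lens must be narrower.
#'
#' @return a 9 x 9 symmetric positive-definite matrix with unit diagonal,
#'   rows/cols: volume, eq_diam, thickness, axial_length, corneal_radius,
#'   eye_weight, eye_eq_diam, body_mass, body_length.
#' @export
default_trait_correlation <- function() {
  size <- c(volume = 0.60, eq_diam = 0.55, thickness = 0.30,
            axial_length = 0.85, corneal_radius = 0.75, eye_weight = 0.90,
            eye_eq_diam = 0.85, body_mass = 0.85, body_length = 0.80)
  lens <- c(volume = 0.55, eq_diam = 0.50, thickness = 0.25,
            axial_length = 0, corneal_radius = 0, eye_weight = 0,
            eye_eq_diam = 0, body_mass = 0, body_length = 0)
  L <- cbind(size, lens)
  R <- L %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(cohort_trait_names, cohort_trait_names)
  eqd <- c(volume = 0.621, eq_diam = 1, thickness = -0.464,
           axial_length = 0.269, corneal_radius = 0.242, eye_weight = 0.290,
           eye_eq_diam = 0.267, body_mass = 0.270, body_length = 0.255)
  R["eq_diam", ] <- eqd
  R[, "eq_diam"] <- eqd
  R
}

#' Specify a synthetic cohort
#'
#' @param n_birds cohort size (default 501, a full study-scale cohort).
#' @param hatch_size nominal birds per hatch (default 20).
#' @param trait_means,trait_sds named numeric vectors (names as in
#'   [default_trait_correlation()]); defaults describe 3-week-old chicks.
#' @param correlation target Spearman correlation matrix (9 x 9).
#' @param shrink_prob_high probability that a hatch is strongly affected by
#'   fixation shrinkage.
#' @param shrink_mean_high,shrink_sd_high distribution of the per-hatch mean
#'   depression depth (mm) for strongly affected hatches.
#' @param shrink_mean_low,shrink_sd_low the same for mildly affected hatches
#'   (folded normal).
#' @param shrink_sd_bird bird-level depression-depth noise (mm).
#' @param global_shrink isotropic shrink factor applied to every lens (1 =
#'   none).
#' @param kidney_threshold_mm depth above which the ground-truth kidney flag
#'   is set.
#' @param us_noise_sd in vivo ultrasound thickness measurement noise (mm).
#' @param mri_noise_sd scan/analysis measurement noise on the model-implied
#'   MRI thickness (mm).
#' @param scan_group_size eyes scanned together (default 16, one array).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_birds = 501, hatch_size = 20,
                        trait_means = NULL, trait_sds = NULL,
                        correlation = default_trait_correlation(),
                        shrink_prob_high = 0.35,
                        shrink_mean_high = 0.35, shrink_sd_high = 0.08,
                        shrink_mean_low = 0.03, shrink_sd_low = 0.02,
                        shrink_sd_bird = 0.07,
                        global_shrink = 1,
                        kidney_threshold_mm = 0.15,
                        us_noise_sd = 0.04, mri_noise_sd = 0.02,
                        scan_group_size = 16) {
  means <- c(volume = 26.4, eq_diam = 4.9, thickness = 2.35,
             axial_length = 9.5, corneal_radius = 3.6, eye_weight = 1.5,
             eye_eq_diam = 10.5, body_mass = 250, body_length = 190)
  sds <- c(volume = 1.2, eq_diam = 0.18, thickness = 0.08,
           axial_length = 0.45, corneal_radius = 0.18, eye_weight = 0.12,
           eye_eq_diam = 0.5, body_mass = 35, body_length = 12)
  if (!is.null(trait_means)) means[names(trait_means)] <- trait_means
  if (!is.null(trait_sds)) sds[names(trait_sds)] <- trait_sds
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-12))
    stop("correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("correlation matrix is not positive semi-definite (eigenvalue %.4g)",
                 min(ev)))
  stopifnot(n_birds >= 1, hatch_size >= 1, global_shrink > 0,
            global_shrink <= 1)
  structure(list(n_birds = n_birds, hatch_size = hatch_size,
                 trait_means = means, trait_sds = sds,
                 correlation = correlation,
                 shrink_prob_high = shrink_prob_high,
                 shrink_mean_high = shrink_mean_high,
                 shrink_sd_high = shrink_sd_high,
                 shrink_mean_low = shrink_mean_low,
                 shrink_sd_low = shrink_sd_low,
                 shrink_sd_bird = shrink_sd_bird,
                 global_shrink = global_shrink,
                 kidney_threshold_mm = kidney_threshold_mm,
                 us_noise_sd = us_noise_sd, mri_noise_sd = mri_noise_sd,
                 scan_group_size = scan_group_size),
            class = "cohort_spec")
}

#' Simulate a bird cohort with ground-truth lens geometry
#'
#' Draws the nine in vivo traits from the Gaussian copula, solves each
#' bird's two-cap lens geometry (anterior flatter than posterior) so that
#' the true volume, equatorial diameter and thickness are mutually
#' consistent, assigns hatches (blocks of about `hatch_size`) and randomized
#' scan groups, draws the hatch-level depression depth mixture, and derives
#' the in vivo ultrasound and model-implied ex vivo MRI thickness readings.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed.
#' @return a data frame (one row per bird) with the trait table, batch
#'   labels and ground truth; the per-bird [lens_spec()]s are attached as
#'   `attr(, "lens_specs")`.
#' @details The sampled copula volume is clamped into the feasible volume
#'   window of the two-cap family with the bird's diameter and thickness
#'   (anterior cap height between 0.15 and 0.5 of thickness), so recorded
#'   ground truth always satisfies the cap equations exactly.
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_birds
  with_seed(seed, function() {
    latent <- 2 * sin(pi * spec$correlation / 6)
    Z <- MASS::mvrnorm(n, mu = rep(0, 9), Sigma = latent)
    traits <- sweep(sweep(Z, 2, spec$trait_sds[cohort_trait_names], `*`),
                    2, spec$trait_means[cohort_trait_names], `+`)
    colnames(traits) <- cohort_trait_names
    T_ax <- pmax(traits[, "thickness"], 0.5)
    geom <- vapply(seq_len(n), function(i) {
      solve_lens_from_traits(traits[i, "volume"],
                             pmax(traits[i, "eq_diam"], 1) / 2, T_ax[i])
    }, numeric(4))
    h_a <- geom[1, ]; R_a <- geom[2, ]; R_p <- geom[3, ]; r_e <- geom[4, ]
    V <- traits[, "volume"]
    # hatches: blocks of about hatch_size, in hatch order
    n_h <- max(1, round(n / spec$hatch_size))
    hatch <- rep(seq_len(n_h), each = ceiling(n / n_h))[seq_len(n)]
    # hatch-level shrinkage mixture
    high <- runif(n_h) < spec$shrink_prob_high
    mu_D <- ifelse(high,
                   rnorm(n_h, spec$shrink_mean_high, spec$shrink_sd_high),
                   abs(rnorm(n_h, spec$shrink_mean_low, spec$shrink_sd_low)))
    D <- pmax(mu_D[hatch] + rnorm(n, 0, spec$shrink_sd_bird), 0)
    D <- pmin(D, 0.79 * h_a * spec$global_shrink)
    kidney <- D > spec$kidney_threshold_mm
    # scan groups: randomized scanning order, arrays of scan_group_size
    ord <- sample.int(n)
    scan_group <- integer(n)
    scan_group[ord] <- ceiling(seq_len(n) / spec$scan_group_size)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    us <- T_ax + rnorm(n, 0, spec$us_noise_sd)
    mri <- spec$global_shrink * (T_ax - D) + rnorm(n, 0, spec$mri_noise_sd)
    out <- data.frame(
      bird_id = seq_len(n), hatch = hatch, scan_group = scan_group,
      sex = sex,
      body_mass_g = traits[, "body_mass"],
      body_length_mm = traits[, "body_length"],
      eye_weight_g = traits[, "eye_weight"],
      eye_eq_diam_mm = traits[, "eye_eq_diam"],
      axial_length_mm = traits[, "axial_length"],
      corneal_radius_mm = traits[, "corneal_radius"],
      us_lens_thickness_mm = us,
      true_T_mm = T_ax, true_eq_diam_mm = 2 * r_e, true_volume_mm3 = V,
      true_Ra_mm = R_a, true_Rp_mm = R_p, true_D_mm = D,
      mri_lens_thickness_mm = mri)
    out$kidney_true <- kidney
    specs <- lapply(seq_len(n), function(i) {
      suppressWarnings(lens_spec(R_a[i], R_p[i], T_ax[i], D = D[i],
                                 shrink = spec$global_shrink))
    })
    attr(out, "lens_specs") <- specs
    out
  })
}

# Pick the two-cap geometry matching the sampled traits. Volume and
# thickness are honored exactly (cap geometry nearly determines volume from
# diameter and thickness, so those two must own their marginals); the
# equatorial radius absorbs the narrow geometric feasibility window: for
# anterior cap heights h_a in [0.15 T, 0.5 T] (anterior surface flatter),
# r_e^2(h_a) = (6 V / pi - h_a^3 - (T - h_a)^3) / (3 T), and the sampled
# radius is clamped into that window before solving for h_a.
solve_lens_from_traits <- function(V, r_e_target, T_ax) {
  re2_of <- function(h) (6 * V / pi - h^3 - (T_ax - h)^3) / (3 * T_ax)
  lo <- 0.15 * T_ax
  hi <- 0.5 * T_ax
  re2 <- min(max(r_e_target^2, re2_of(lo) + 1e-9), re2_of(hi) - 1e-9)
  if (re2 <= 0) stop("sampled volume too small for the thickness margin")
  h_a <- uniroot(function(h) re2_of(h) - re2, c(lo, hi), tol = 1e-10)$root
  h_p <- T_ax - h_a
  R_a <- (re2 + h_a^2) / (2 * h_a)
  R_p <- (re2 + h_p^2) / (2 * h_p)
  c(h_a, R_a, R_p, sqrt(re2))
}

#' Write / read a cohort table as CSV
#'
#' @param cohort data frame from [simulate_cohort()].
#' @param path destination `.csv`.
#' @return the path (write) or the data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Build an eye phantom for one cohort row
#'
#' @param cohort_row one row of the [simulate_cohort()] table.
#' @param lens the matching [lens_spec()] (from `attr(cohort, "lens_specs")`).
#' @param ... passed to [eye_spec()].
#' @return an [eye_spec()] sized from the bird's eye traits.
#' @export
cohort_eye <- function(cohort_row, lens, ...) {
  eye_spec(lens,
           axial_length = max(cohort_row$axial_length_mm, 8),
           eq_diameter = max(cohort_row$eye_eq_diam_mm, 9), ...)
}
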
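# Synthetic cohort generation: copula recovery, hatch-level shrinkage,
# ground-truth geometry consistency.

test_that("the default trait correlation target is a valid matrix", {
  R <- default_trait_correlation()
  expect_equal(dim(R), c(9, 9))
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 9))
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("a targeted rank correlation is recovered at n = 500", {
  R <- diag(9)
  dimnames(R) <- dimnames(default_trait_correlation())
  R["volume", "eye_weight"] <- R["eye_weight", "volume"] <- 0.6
  spec <- cohort_spec(n_birds = 500, correlation = R)
  coh <- simulate_cohort(spec, seed = 5)
  rho <- spearman(coh$true_volume_mm3, coh$eye_weight_g)$rho
  expect_lt(abs(rho - 0.6), 0.08)
})

test_that("the full default correlation structure is recovered within 3 SE", {
  spec <- cohort_spec(n_birds = 500)
  coh <- simulate_cohort(spec, seed = 8)
  cols <- c(volume = "true_volume_mm3", eq_diam = "true_eq_diam_mm",
            axial_length = "axial_length_mm", eye_weight = "eye_weight_g",
            body_mass = "body_mass_g")
  R <- default_trait_correlation()
  se <- 1 / sqrt(500 - 3)
  for (a in names(cols)) for (b in names(cols)) {
    if (a >= b) next
    z_target <- atanh(R[a, b])
    z_sample <- atanh(spearman(coh[[cols[a]]], coh[[cols[b]]])$rho)
    expect_lt(abs(z_sample - z_target), 3 * se + 0.03)
  }
})

test_that("a non-PSD target matrix is rejected, naming the eigenvalue", {
  R <- diag(9)
  dimnames(R) <- dimnames(default_trait_correlation())
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9
  expect_error(cohort_spec(correlation = R), "eigenvalue")
})

test_that("zero shrinkage gives biconvex lenses and matched thickness reads", {
  spec <- cohort_spec(n_birds = 200, shrink_prob_high = 0,
                      shrink_mean_low = 0, shrink_sd_low = 1e-12,
                      shrink_sd_bird = 1e-12)
  coh <- simulate_cohort(spec, seed = 9)
  expect_true(all(coh$true_D_mm < 1e-6))
  expect_false(any(coh$kidney_true))
  expect_lt(mean(abs(coh$mri_lens_thickness_mm - coh$us_lens_thickness_mm)),
            0.06)
  expect_gt(spearman(coh$mri_lens_thickness_mm,
                     coh$us_lens_thickness_mm)$rho, 0.7)
})

test_that("hatches hold about 20 birds and scanning is randomized into 16s", {
  coh <- simulate_cohort(cohort_spec(n_birds = 500, hatch_size = 20), seed = 2)
  expect_equal(length(unique(coh$hatch)), 25)
  expect_true(all(table(coh$hatch) == 20))
  expect_equal(max(coh$scan_group), ceiling(500 / 16))
  # scan groups must cut across hatches (randomized order)
  expect_gt(mean(tapply(coh$scan_group, coh$hatch,
                        function(g) length(unique(g)))), 5)
})

test_that("ground truth is exactly consistent with the cap equations", {
  coh <- simulate_cohort(cohort_spec(n_birds = 50), seed = 3)
  for (i in c(1, 17, 50)) {
    g <- solve_biconvex_geometry(coh$true_Ra_mm[i], coh$true_Rp_mm[i],
                                 coh$true_T_mm[i])
    expect_equal(2 * g$r_e, coh$true_eq_diam_mm[i], tolerance = 1e-6)
    expect_equal(g$volume, coh$true_volume_mm3[i], tolerance = 1e-6)
  }
  specs <- attr(coh, "lens_specs")
  expect_length(specs, 50)
  expect_s3_class(specs[[1]], "lens_spec")
})

test_that("cohorts are deterministic under a fixed seed", {
  c1 <- simulate_cohort(cohort_spec(n_birds = 60), seed = 11)
  c2 <- simulate_cohort(cohort_spec(n_birds = 60), seed = 11)
  c3 <- simulate_cohort(cohort_spec(n_birds = 60), seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1$true_D_mm, c3$true_D_mm))
})

test_that("cohort CSV round trip keeps the table", {
  coh <- simulate_cohort(cohort_spec(n_birds = 25), seed = 13)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_equal(back$true_T_mm, coh$true_T_mm, tolerance = 1e-12)
  expect_equal(names(back)[1:4], c("bird_id", "hatch", "scan_group", "sex"))
})

test_that("kidney prevalence sits near one third under defaults", {
  coh <- simulate_cohort(cohort_spec(n_birds = 500), seed = 21)
  expect_gt(mean(coh$kidney_true), 0.15)
  expect_lt(mean(coh$kidney_true), 0.55)
})
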
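# Rank correlation, normality screening, paired comparison, logistic LRT,
# repeatability table and correlation map.

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(1)
  x <- rnorm(40)
  y <- 2 * x + rnorm(40, 0, 0.5)
  r1 <- spearman(x, y)
  r2 <- spearman(exp(x), y)
  r3 <- spearman(x, y^3 + 5 * y)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$rho, r3$rho, tolerance = 1e-12)
  expect_equal(spearman(x, x^3)$rho, 1)
})

test_that("small-sample p equals the exhaustive permutation distribution", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  res <- spearman(x, y)
  # independent oracle: enumerate all 4! permutations directly
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- as.matrix(perms[apply(perms, 1, function(p) length(unique(p)) == 4), ])
  rhos <- apply(perms, 1, function(p) cor(x, y[p]))
  p_oracle <- mean(abs(rhos) >= abs(cor(rank(x), rank(y))) - 1e-12)
  expect_equal(res$rho, 0.6)
  expect_equal(res$p, p_oracle)
})

test_that("Spearman equals Pearson on midranks under ties", {
  x <- c(1, 2, 2, 3, 4, 4, 4)
  y <- c(5, 3, 3, 2, 2, 1, 1)
  expect_equal(spearman(x, y)$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("Spearman input validation", {
  expect_error(spearman(1:2, 2:3), "at least 3")
  expect_error(spearman(c(1, 1, 1, 1), 1:4), "zero-variance")
  expect_error(spearman(1:4, 1:5), "equal length")
  # pairwise-complete deletion
  expect_equal(spearman(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))$n, 3)
})

test_that("normality screening detects strong skew and rejects constants", {
  set.seed(2)
  x <- exp(rnorm(300, 0, 1))
  expect_lt(ks_normality(x)$p, 0.005)
  z <- rnorm(300)
  expect_gt(ks_normality(z)$p, 0.01)
  expect_error(ks_normality(rep(1, 20)), "constant")
  expect_error(ks_normality(rnorm(4)), "at least 5")
  # the fixed-parameter variant is the classical KS test
  res <- ks_normality(z, estimated = FALSE)
  ref <- suppressWarnings(ks.test(z, "pnorm"))
  expect_equal(res$D, unname(ref$statistic))
})

test_that("paired t: limiting behavior and validation", {
  set.seed(3)
  x <- rnorm(20)
  res <- paired_t(x, x + 1 + rnorm(20, 0, 1e-4))
  expect_lt(res$p, 1e-10)
  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("logistic LRT is zero for exactly balanced per-level proportions", {
  outcome <- rep(c(1, 1, 0, 0, 0), times = 4)
  fac <- rep(letters[1:4], each = 5)
  res <- logistic_lrt(outcome, fac)
  expect_equal(res$deviance_diff, 0, tolerance = 1e-9)
  expect_equal(res$p, 1, tolerance = 1e-6)
})

test_that("logistic LRT on a 2x2 table matches the closed-form deviance", {
  # counts: group A 20 successes / 5 failures, group B 5 / 20
  outcome <- c(rep(1, 20), rep(0, 5), rep(1, 5), rep(0, 20))
  fac <- rep(c("A", "B"), each = 25)
  res <- logistic_lrt(outcome, fac)
  loglik <- function(k, n) {
    p <- k / n
    ifelse(p %in% c(0, 1), 0, k * log(p) + (n - k) * log(1 - p))
  }
  # saturated-by-level vs pooled binomial log-likelihood difference
  ll1 <- loglik(20, 25) + loglik(5, 25)
  ll0 <- loglik(25, 50)
  expect_equal(res$deviance_diff, 2 * (ll1 - ll0), tolerance = 1e-8)
  expect_equal(res$df, 1)
})

test_that("logistic LRT validation and separation warning", {
  expect_error(logistic_lrt(c(0, 1, 0, 1), rep("a", 4)), "2 levels")
  expect_error(logistic_lrt(rep(1, 10), rep(c("a", "b"), 5)), "both classes")
  expect_warning(
    logistic_lrt(c(rep(1, 10), rep(0, 10), rep(c(0, 1), 5)),
                 rep(c("a", "b", "c"), c(10, 10, 10))),
    "separation")
})

test_that("repeatability table: identical scans give r = 1 on every trait", {
  set.seed(4)
  scan <- data.frame(id = 1:12,
                     thickness_mm = rnorm(12, 2.3, 0.1),
                     eq_diam_mm = rnorm(12, 4.9, 0.2),
                     volume_mm3 = rnorm(12, 26, 1),
                     Ra_mm = rnorm(12, 3, 0.2), Rp_mm = rnorm(12, 3.4, 0.2),
                     kidney = rep(c(TRUE, FALSE), 6))
  scan2 <- scan
  for (tr in c("thickness_mm", "eq_diam_mm", "volume_mm3", "Ra_mm", "Rp_mm"))
    scan2[[tr]] <- scan[[tr]] + rnorm(12, 0, 1e-9)
  tab <- repeatability_table(scan, scan2)
  expect_equal(nrow(tab), 10)   # 5 traits x 2 strata
  expect_true(all(tab$r > 0.999))
  expect_equal(unique(tab$n[tab$stratum == "non_kidney"]), 6)
  # unmatched ids
  scan3 <- scan; scan3$id <- 100 + scan3$id
  expect_error(repeatability_table(scan, scan3), "matched ids")
})

test_that("correlation map recovers a planted dependence structure", {
  set.seed(5)
  n <- 300
  size <- rnorm(n)
  traits <- data.frame(
    volume = size + rnorm(n, 0, 0.6),
    eq_diam = size + rnorm(n, 0, 0.7),
    curvature = rnorm(n),             # independent of everything
    body_mass = size + rnorm(n, 0, 0.5),
    eye_weight = size + rnorm(n, 0, 0.5))
  # alpha 0.01: at 10 raw tests, a planted-null trait would otherwise pick
  # up spurious 0.05-level edges often enough to make the check flaky
  cm <- correlation_map(traits, c("volume", "eq_diam", "curvature"),
                        c("body_mass", "eye_weight"), alpha = 0.01)
  edges <- cm$all$edges
  has_edge <- function(a, b) any((edges$trait_a == a & edges$trait_b == b) |
                                   (edges$trait_a == b & edges$trait_b == a))
  expect_true(has_edge("volume", "body_mass"))
  expect_true(has_edge("eq_diam", "eye_weight"))
  expect_false(has_edge("curvature", "body_mass"))
  expect_false(has_edge("curvature", "eye_weight"))
  expect_equal(cm$all$rho["volume", "volume"], 1)
})

test_that("correlation map strata and validation", {
  set.seed(6)
  traits <- data.frame(a = rnorm(20), b = rnorm(20))
  keep <- c(rep(TRUE, 12), rep(FALSE, 8))
  cm <- correlation_map(traits, "a", "b", strata = list(sub = keep))
  expect_equal(cm$sub$n["a", "b"], 12)
  expect_error(correlation_map(traits, "a", "b",
                               strata = list(none = rep(FALSE, 20))), "empty")
  expect_error(correlation_map(traits, "a", character(0)), "at least two")
  expect_error(correlation_map(traits, "a", "missing_col"), "missing")
})

test_that("correlation graph JSON export round-trips", {
  set.seed(7)
  traits <- data.frame(a = rnorm(30), b = rnorm(30) )
  traits$c <- traits$a + rnorm(30, 0, 0.3)
  cm <- correlation_map(traits, c("a", "b"), "c")
  f <- tempfile(fileext = ".json")
  write_correlation_graph(cm$all, f)
  g <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(g$nodes$id, c("a", "b", "c"))
  expect_true(all(g$edges$weight >= 0))
})
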
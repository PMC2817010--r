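## The trait-analysis layer: Spearman rank correlation (midranks; exact
## permutation p for small n, t approximation otherwise), Lilliefors
## normality screening, paired t comparisons, logistic likelihood-ratio
## tests of batch factors, the repeat-scan repeatability table and the
## all-pairs trait correlation map.

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties. The two-sided p-value uses the
#' exact permutation distribution for `n < 10` and the t approximation
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df) otherwise. Incomplete
#' pairs are dropped (pairwise-complete deletion).
#'
#' @param x,y numeric vectors of equal length.
#' @return an object of class `correlation_result`: `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("correlation undefined: zero-variance ranks")
  rho <- cor(rx, ry)
  if (n < 10) {
    perms <- permutations_of(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- (matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, p = min(p, 1), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.3g)\n", x$rho, x$n, x$p))
  invisible(x)
}

# all permutations of 1:n as a matrix (n! rows); n <= 9
permutations_of <- function(n) {
  if (n > 9) stop("exact permutation enumeration limited to n <= 9")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}

#' Normality screening (Kolmogorov-Smirnov family)
#'
#' Default is the Lilliefors variant, appropriate when the normal parameters
#' are estimated from the sample (as in trait screening). The
#' fixed-parameter one-sample KS test is available for a fully specified
#' reference normal.
#'
#' @param x numeric vector, `n >= 5`.
#' @param estimated `TRUE` (Lilliefors, default) or `FALSE` for the
#'   classical KS test against `N(mean, sd)`.
#' @param mean,sd reference parameters when `estimated = FALSE` (default:
#'   standard normal).
#' @return list with statistic `D` and `p`.
#' @export
ks_normality <- function(x, estimated = TRUE, mean = 0, sd = 1) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need at least 5 observations")
  if (sd(x) == 0) stop("constant vector: normality test undefined")
  if (estimated) {
    ht <- nortest::lillie.test(x)
  } else {
    ht <- ks.test(x, "pnorm", mean = mean, sd = sd)
  }
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Paired t test
#'
#' Standard two-sided paired t comparison of matched measurements.
#'
#' @param x1,x2 numeric vectors of equal length (`n >= 2`).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  ok <- complete.cases(x1, x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) < 2) stop("need at least 2 complete pairs")
  d <- x1 - x2
  if (sd(d) == 0) stop("zero-variance differences: paired t undefined")
  ht <- t.test(x1, x2, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_diff = unname(ht$estimate))
}

#' Logistic likelihood-ratio test of a categorical factor
#'
#' Fits `outcome ~ factor` by IRLS (binomial logit) against the
#' intercept-only model and reports the likelihood-ratio test: the deviance
#' difference on `levels - 1` df. Levels with complete separation (all 0 or
#' all 1) are reported with a warning; the LRT remains defined because the
#' saturated per-level likelihood is finite.
#'
#' @param outcome logical or 0/1 vector.
#' @param factor categorical variable (coerced to factor).
#' @return an object of class `logistic_lrt`: `deviance_diff`, `df`, `p`,
#'   and `proportions` (per-level fitted outcome proportions with counts).
#' @export
logistic_lrt <- function(outcome, factor) {
  outcome <- as.integer(as.logical(outcome))
  factor <- droplevels(as.factor(factor))
  if (length(outcome) != length(factor)) stop("outcome and factor lengths differ")
  ok <- complete.cases(outcome, factor)
  outcome <- outcome[ok]; factor <- droplevels(factor[ok])
  if (nlevels(factor) < 2) stop("factor needs at least 2 levels")
  if (length(unique(outcome)) < 2)
    stop("outcome must include both classes")
  prop <- tapply(outcome, factor, mean)
  cnt <- tapply(outcome, factor, length)
  if (any(prop %in% c(0, 1)))
    warning("complete separation in some factor levels; per-level estimates are degenerate")
  fit1 <- suppressWarnings(glm(outcome ~ factor, family = binomial()))
  fit0 <- suppressWarnings(glm(outcome ~ 1, family = binomial()))
  dd <- fit0$deviance - fit1$deviance
  df <- nlevels(factor) - 1
  structure(list(deviance_diff = max(dd, 0), df = df,
                 p = pchisq(max(dd, 0), df = df, lower.tail = FALSE),
                 proportions = data.frame(level = names(prop),
                                          n = as.integer(cnt),
                                          proportion = as.numeric(prop))),
            class = "logistic_lrt")
}

#' @export
print.logistic_lrt <- function(x, ...) {
  cat(sprintf("logistic LRT: deviance diff = %.3f on %d df, p = %.3g\n",
              x$deviance_diff, x$df, x$p))
  invisible(x)
}

#' Repeat-scan repeatability table
#'
#' Correlates the lens measurements of two scans of the same eyes, one row
#' per trait (thickness, equatorial diameter, volume, anterior and posterior
#' radius), with the paired t comparison alongside, for all eyes and for the
#' stratum of eyes non-kidney-shaped in both scans.
#'
#' @param scan1,scan2 data frames with an `id` column, the five measurement
#'   columns (`thickness_mm`, `eq_diam_mm`, `volume_mm3`, `Ra_mm`, `Rp_mm`)
#'   and a logical `kidney` column.
#' @return data frame with columns `stratum`, `trait`, `n`, `r`, `p_cor`,
#'   `t`, `p_t`.
#' @export
repeatability_table <- function(scan1, scan2) {
  traits <- c("thickness_mm", "eq_diam_mm", "volume_mm3", "Ra_mm", "Rp_mm")
  need <- c("id", traits, "kidney")
  if (!all(need %in% names(scan1)) || !all(need %in% names(scan2)))
    stop("scans must carry columns: ", paste(need, collapse = ", "))
  m <- merge(scan1, scan2, by = "id", suffixes = c(".1", ".2"))
  if (nrow(m) < 3) stop("fewer than 3 matched ids across scans")
  strata <- list(all = rep(TRUE, nrow(m)),
                 non_kidney = !m$kidney.1 & !m$kidney.2)
  out <- do.call(rbind, lapply(names(strata), function(s) {
    sel <- strata[[s]]
    do.call(rbind, lapply(traits, function(tr) {
      x1 <- m[[paste0(tr, ".1")]][sel]
      x2 <- m[[paste0(tr, ".2")]][sel]
      cr <- spearman(x1, x2)
      tt <- paired_t(x1, x2)
      data.frame(stratum = s, trait = tr, n = cr$n, r = cr$rho, p_cor = cr$p,
                 t = tt$t, p_t = tt$p)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' All-pairs trait correlation map
#'
#' Computes Spearman correlations between every pair of traits in the given
#' strata and extracts the significance graph (edges where p < alpha), the
#' structure used to compare lens measurements against eye and body size.
#'
#' @param traits data frame of numeric trait columns (plus any columns named
#'   in `strata` definitions).
#' @param lens_traits,other_traits character vectors naming the two trait
#'   groups; edges are reported for all pairs among their union.
#' @param strata named list of logical vectors (row selections); default a
#'   single stratum `all`.
#' @param alpha significance level for graph edges (default 0.05, no
#'   multiplicity adjustment, mirroring raw-p reporting; set
#'   `holm = TRUE` to apply a Holm correction).
#' @param holm apply Holm correction to the edge p-values.
#' @return list per stratum, each with `rho` and `p` matrices, `n` matrix of
#'   pair counts, and `edges` (data frame: trait_a, trait_b, rho, p).
#' @export
correlation_map <- function(traits, lens_traits, other_traits,
                            strata = list(all = NULL), alpha = 0.05,
                            holm = FALSE) {
  vars <- c(lens_traits, other_traits)
  missing_v <- setdiff(vars, names(traits))
  if (length(missing_v)) stop("missing trait columns: ",
                              paste(missing_v, collapse = ", "))
  if (length(vars) < 2) stop("need at least two traits")
  lapply(setNames(names(strata), names(strata)), function(s) {
    sel <- strata[[s]] %||% rep(TRUE, nrow(traits))
    dat <- traits[sel, vars, drop = FALSE]
    if (nrow(dat) == 0) stop("empty stratum: ", s)
    k <- length(vars)
    rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
    diag(rho) <- 1; diag(p) <- 0; diag(nmat) <- colSums(!is.na(dat))
    pairs <- combn(k, 2)
    for (c0 in seq_len(ncol(pairs))) {
      i <- pairs[1, c0]; j <- pairs[2, c0]
      ok <- complete.cases(dat[[i]], dat[[j]])
      if (sum(ok) < 3) stop(sprintf("fewer than 3 complete rows for %s vs %s",
                                    vars[i], vars[j]))
      cr <- spearman(dat[[i]], dat[[j]])
      rho[i, j] <- rho[j, i] <- cr$rho
      p[i, j] <- p[j, i] <- cr$p
      nmat[i, j] <- nmat[j, i] <- cr$n
    }
    pv <- p[upper.tri(p)]
    if (holm) {
      adj <- p.adjust(pv, "holm")
      p[upper.tri(p)] <- adj
      p[lower.tri(p)] <- t(p)[lower.tri(p)]
    }
    ut <- which(upper.tri(p), arr.ind = TRUE)
    edges <- data.frame(trait_a = vars[ut[, 1]], trait_b = vars[ut[, 2]],
                        rho = rho[ut], p = p[ut], n = nmat[ut])
    edges <- edges[edges$p < alpha, , drop = FALSE]
    rownames(edges) <- NULL
    list(rho = rho, p = p, n = nmat, edges = edges, stratum = s)
  })
}

#' Write a correlation map as a JSON graph
#'
#' Nodes are traits; edges carry the correlation magnitude as weight (the
#' rendering convention: line thickness proportional to |rho|).
#'
#' @param cmap one stratum element from [correlation_map()].
#' @param path destination `.json` path.
#' @return the path, invisibly.
#' @export
write_correlation_graph <- function(cmap, path) {
  nodes <- data.frame(id = rownames(cmap$rho))
  edges <- cmap$edges
  edges$weight <- abs(edges$rho)
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
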
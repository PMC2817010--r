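## Internal helpers: deterministic seed streams, local RNG scope,
## trilinear sampling, small numerics.

#' Derive a reproducible child seed from a top-level seed and a stream id
#'
#' Mixes `(seed, id)` into a 31-bit integer with exact modular arithmetic so
#' that per-eye / per-stage random streams are stable across platforms and
#' independent of the order in which eyes are processed.
#'
#' @param seed integer top-level seed.
#' @param id integer stream identifier (e.g. eye number).
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
child_seed <- function(seed, id) {
  m <- 2147483647 # 2^31 - 1, prime
  a <- as.numeric(seed) %% m
  b <- as.numeric(id) %% m
  h <- mulmod31(a + 1, 48271, m)
  h <- (h + mulmod31(b + 1, 69621, m)) %% m
  h <- mulmod31(h + 1, 630360016, m)
  h <- (h + 12345) %% m
  if (h < 1) h <- h + 1
  as.integer(h)
}

# exact (a * b) mod m for a, b < 2^31 using 16-bit splitting (stays < 2^53)
mulmod31 <- function(a, b, m) {
  a <- a %% m
  b_hi <- floor(b / 65536)
  b_lo <- b - b_hi * 65536
  (((a * b_hi) %% m) * 65536 + a * b_lo) %% m
}

# Evaluate `fn` with the RNG seeded to `seed`, restoring global RNG state.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Trilinear interpolation of a 3D array at continuous voxel coordinates
# (1-based; voxel centers at integers). Points outside the grid return
# `outside`.
trilinear <- function(arr, pts, outside = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(outside, length(x))
  if (!any(ok)) return(out)
  x <- pmin(pmax(x[ok], 1), d[1]); y <- pmin(pmax(y[ok], 1), d[2])
  z <- pmin(pmax(z[ok], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- (x0 - 1) + (y0 - 1) * nx + (z0 - 1) * nxy + 1
  v000 <- arr[base];             v100 <- arr[base + 1]
  v010 <- arr[base + nx];        v110 <- arr[base + nx + 1]
  v001 <- arr[base + nxy];       v101 <- arr[base + nxy + 1]
  v011 <- arr[base + nx + nxy];  v111 <- arr[base + nx + nxy + 1]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out
}

# Normalize a vector to unit length.
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Two unit vectors spanning the plane orthogonal to unit vector `u`.
orthobasis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitize(pracma_cross(ref, u))
  e2 <- pracma_cross(u, e1)
  rbind(e1, e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer-array shift with NA padding (3D)
shift3i <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(NA_integer_, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}
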
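## Powell's direction-set minimization (derivative-free). Line
## minimizations use Brent's method via stats::optimize with automatic
## bracket expansion; the direction of largest decrease is replaced by the
## net displacement when the standard Powell acceptance test passes.

#' Minimize a function with Powell's direction-set method
#'
#' @param fn objective, `fn(par, ...) -> numeric(1)`.
#' @param par numeric start vector.
#' @param ... further arguments passed to `fn`.
#' @param step initial line-search half-width per coordinate (scalar or
#'   vector).
#' @param ptol convergence tolerance on the parameter step (max absolute
#'   component change per iteration).
#' @param ftol relative convergence tolerance on the objective.
#' @param maxit maximum number of direction-set sweeps.
#' @return list with `par`, `value`, `iterations`, `converged`.
#' @export
powell <- function(fn, par, ..., step = 0.5, ptol = 1e-6, ftol = 1e-12,
                   maxit = 200) {
  n <- length(par)
  step <- rep_len(step, n)
  dirs <- diag(step, n, n)
  x <- as.numeric(par)
  fx <- fn(x, ...)
  line_min <- function(x0, d, f0) {
    if (all(d == 0)) return(list(x = x0, f = f0, alpha = 0))
    lo <- -1; hi <- 1
    for (rep in 1:12) {
      o <- optimize(function(a) fn(x0 + a * d, ...), lower = lo, upper = hi,
                    tol = 1e-10)
      edge <- min(o$minimum - lo, hi - o$minimum) < 0.05 * (hi - lo)
      if (!edge) break
      lo <- lo * 4; hi <- hi * 4
    }
    if (o$objective < f0) list(x = x0 + o$minimum * d, f = o$objective,
                               alpha = o$minimum)
    else list(x = x0, f = f0, alpha = 0)
  }
  converged <- FALSE
  it <- 0
  while (it < maxit) {
    it <- it + 1
    x_start <- x
    f_start <- fx
    biggest <- 0
    ibig <- 1
    for (i in seq_len(n)) {
      f_before <- fx
      r <- line_min(x, dirs[, i], fx)
      x <- r$x; fx <- r$f
      if (f_before - fx > biggest) {
        biggest <- f_before - fx
        ibig <- i
      }
    }
    dx <- x - x_start
    if (max(abs(dx)) < ptol &&
        2 * (f_start - fx) <= ftol * (abs(f_start) + abs(fx)) + 1e-300) {
      converged <- TRUE
      break
    }
    # Powell's acceptance test for replacing a direction with the net step
    xe <- x_start + 2 * dx
    fe <- fn(xe, ...)
    if (fe < f_start) {
      t_stat <- 2 * (f_start - 2 * fx + fe) *
        (f_start - fx - biggest)^2 - biggest * (f_start - fe)^2
      if (t_stat < 0) {
        r <- line_min(x, dx, fx)
        x <- r$x; fx <- r$f
        dirs[, ibig] <- dirs[, n]
        dirs[, n] <- dx
      }
    }
  }
  list(par = x, value = fx, iterations = it, converged = converged)
}
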
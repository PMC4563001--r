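# Powell's direction-set minimizer.
#
# Classic derivative-free scheme: cycle through a set of search directions,
# line-minimizing along each (Brent via stats::optimize); after each cycle,
# replace the direction of largest single decrease with the net cycle
# displacement and line-minimize along it. No installed package exposes this
# method, so it is implemented here; it is the local optimizer of the
# registration (see optimize_powell).
#
# fn: objective over a numeric parameter vector.
# x0: start point. scale: initial step per dimension (sets both the initial
# direction lengths and the line-search bracket, in each parameter's units).
# Returns list(par, value, converged, n_evaluations).
powell_minimize <- function(fn, x0, scale, ftol = 1e-4, ptol = 1e-3,
                            maxeval = 2000, max_cycles = 30) {
  n <- length(x0)
  stopifnot(length(scale) == n, all(scale > 0))
  evals <- 0L
  f <- function(x) {
    evals <<- evals + 1L
    fn(x)
  }
  # line minimization along direction u from x; bracket t in [-1.2, 1.2]
  # (directions carry their own scale)
  line_min <- function(x, u, fx) {
    if (sqrt(sum(u^2)) < 1e-12) {
      return(list(x = x, value = fx, t = 0))
    }
    g <- function(t) f(x + t * u)
    opt <- stats::optimize(g, interval = c(-1.2, 1.2), tol = 1e-4)
    if (opt$objective < fx) {
      list(x = x + opt$minimum * u, value = opt$objective, t = opt$minimum)
    } else {
      list(x = x, value = fx, t = 0)
    }
  }
  dirs <- diag(scale, nrow = n)
  x <- x0
  fx <- f(x)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    x_start <- x
    f_start <- fx
    biggest <- 0
    ibig <- 1L
    for (i in seq_len(n)) {
      res <- line_min(x, dirs[, i], fx)
      if (fx - res$value > biggest) {
        biggest <- fx - res$value
        ibig <- i
      }
      x <- res$x
      fx <- res$value
      if (evals >= maxeval) break
    }
    # replace the direction of largest decrease with the cycle displacement
    disp <- x - x_start
    if (sqrt(sum(disp^2)) > 1e-12 && evals < maxeval) {
      res <- line_min(x, disp, fx)
      x <- res$x
      fx <- res$value
      dirs[, ibig] <- disp
    }
    if (2 * abs(f_start - fx) <= ftol * (abs(f_start) + abs(fx)) + 1e-12 ||
        max(abs(x - x_start)) < ptol) {
      converged <- TRUE
      break
    }
    if (evals >= maxeval) break
  }
  list(par = x, value = fx, converged = converged, n_evaluations = evals)
}
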
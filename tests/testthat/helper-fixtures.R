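# Shared fixtures: small grids, a coarse contour discretization for fast
# SCFT solves, and the analytic two-well landscape used to validate the
# string method against brute-force search.

fast_params <- function(mu = 0, ...) {
  scft_params(mu = mu, ds = 0.02, ...)
}

# two-well landscape on (x, y): quadratic double well along x, harmonic
# confinement in y, and a Gaussian ridge at the origin.  Coefficients are
# fixed here; the ridge is weak enough that the saddle stays at the origin.
twowell_energy <- function(v) {
  x <- v[1]; y <- v[2]
  (x^2 - 1)^2 + 2 * y^2 + 0.2 * exp(-4 * (x^2 + y^2))
}

twowell_grad <- function(v) {
  x <- v[1]; y <- v[2]
  g <- exp(-4 * (x^2 + y^2))
  c(4 * x * (x^2 - 1) - 1.6 * x * g,
    4 * y - 1.6 * y * g)
}

twowell_minimum <- function() {
  stats::optim(c(1, 0), twowell_energy, twowell_grad, method = "BFGS",
               control = list(reltol = 1e-14))
}

# brute-force minimax oracle: the lowest energy level at which the two
# basins become connected on a fine grid (binary search over the level,
# flood fill for connectivity)
twowell_saddle_bruteforce <- function(n = 241, lim = 1.6) {
  xs <- seq(-lim, lim, length.out = n)
  E <- outer(xs, xs, function(x, y)
    (x^2 - 1)^2 + 2 * y^2 + 0.2 * exp(-4 * (x^2 + y^2)))
  i_a <- c(which.min(abs(xs + 1)), which.min(abs(xs)))
  i_b <- c(which.min(abs(xs - 1)), which.min(abs(xs)))
  connected <- function(level) {
    open <- E <= level
    if (!open[i_a[1], i_a[2]] || !open[i_b[1], i_b[2]]) return(FALSE)
    lab <- matrix(FALSE, n, n)
    stack <- list(i_a)
    lab[i_a[1], i_a[2]] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (cur[1] == i_b[1] && cur[2] == i_b[2]) return(TRUE)
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
        if (ni >= 1 && ni <= n && nj >= 1 && nj <= n &&
            open[ni, nj] && !lab[ni, nj]) {
          lab[ni, nj] <- TRUE
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
    FALSE
  }
  lo <- min(E[i_a[1], i_a[2]], E[i_b[1], i_b[2]])
  hi <- max(E)
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (connected(mid)) hi <- mid else lo <- mid
  }
  hi
}

# string relaxation on the two-well landscape with M nodes; returns the
# barrier estimate (max F minus initial-minimum F)
twowell_string_barrier <- function(M, n_outer = 400, inner_steps = 5,
                                   step = 0.02) {
  opt <- twowell_minimum()
  a <- opt$par * c(-1, 1); b <- opt$par
  nodes <- lapply(seq(0, 1, length.out = M), function(f)
    (1 - f) * a + f * b + c(0, 0.3 * sin(pi * f)))
  path <- string_path(nodes)
  relax_fun <- function(v, steps) {
    if (steps > 0) for (i in seq_len(steps)) v <- v - step * twowell_grad(v)
    list(node = v, metric = v, energy = twowell_energy(v))
  }
  res <- string_relax(path, relax_fun, n_outer = n_outer,
                      inner_steps = inner_steps, tol = 1e-10)
  list(barrier = max(res$profile$F) - res$profile$F[1], res = res)
}
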
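# Locating chemical potentials that realize prescribed tensions.
#
# The planar bilayer tension is a smooth, strictly decreasing function of
# the exchange chemical potential: raising mu feeds lipid from the
# reservoir into the membrane, relaxing its tension (by Gibbs adsorption,
# d sigma / d mu equals minus the excess lipid per unit area).  The
# solvers below evaluate sigma(mu) by full SCFT convergence at each mu,
# warm-starting every solve from the previous converged fields so a
# bisection costs only a handful of cheap restarts.

#' Planar tension as a function of the exchange chemical potential
#'
#' Returns a stateful evaluator `f(mu)` that converges the planar bilayer
#' at `mu` (warm-starting from the last converged fields) and returns the
#' tension in model units.  The most recent `scft_state` is kept in
#' `environment(f)$last_state`.
#'
#' @param params an [scft_params()] object (its `mu` is overridden).
#' @param grid a `planar1d` [make_grid()].
#' @param init initial fields; defaults to a centered
#'   [seed_topology()] planar bilayer.
#' @param ... passed to [scft_converge()].
#' @return A function `mu -> sigma` (model units).
#' @export
planar_tension_fn <- function(params, grid, init = NULL, ...) {
  stopifnot(grid$kind == "planar1d")
  if (is.null(init))
    init <- seed_topology("planar_bilayer", grid, params)
  last_fields <- init
  last_state <- NULL
  dots <- list(...)
  if (is.null(dots$max_iter)) dots$max_iter <- 4000
  f <- function(mu) {
    st <- do.call(scft_converge,
                  c(list(init = last_fields, params = set_mu(params, mu),
                         grid = grid), dots))
    if (max(st$dens$phi_tail) < 0.2)
      stop(sprintf("bilayer dissolved at mu = %g (outside the metastable range)",
                   mu))
    last_fields <<- st$fields
    last_state <<- st
    st$excess_free_energy
  }
  f
}

# bisection on a strictly decreasing function g(mu) with bracket expansion
bisect_decreasing <- function(g, lo, hi, tol_g, max_expand = 8) {
  flo <- g(lo); fhi <- g(hi)
  width <- hi - lo
  for (k in seq_len(max_expand)) {
    if (flo > 0 && fhi < 0) break
    if (flo < 0) { lo <- lo - width; flo <- g(lo) }
    if (fhi > 0) { hi <- hi + width; fhi <- g(hi) }
  }
  if (!(flo > 0 && fhi < 0)) stop("could not bracket the root")
  repeat {
    mid <- (lo + hi) / 2
    fm <- g(mid)
    if (abs(fm) < tol_g || (hi - lo) < 1e-12) break
    if (fm < 0) hi <- mid else lo <- mid
  }
  list(mu = mid, g = fm)
}

#' Chemical potential of the tensionless planar bilayer
#'
#' Bisection for the `mu*` at which the planar bilayer's excess free
#' energy per area vanishes; `sigma(mu)` is strictly decreasing, positive
#' below `mu*` and negative above it.  The initial bracket is expanded
#' until the tension changes sign.
#'
#' @inheritParams planar_tension_fn
#' @param bracket initial `mu` bracket.
#' @param tol_sigma tolerance on the tension at the root (model units).
#' @param max_expand bracket-expansion attempts.
#' @return A list with `mu` (the tensionless value), `sigma` (residual
#'   tension), and `state` (the converged bilayer at `mu`).
#' @export
find_tensionless_mu <- function(params, grid, init = NULL,
                                bracket = c(10, 12), tol_sigma = 1e-5,
                                max_expand = 8, ...) {
  f <- planar_tension_fn(params, grid, init, ...)
  root <- bisect_decreasing(f, bracket[1], bracket[2], tol_sigma,
                            max_expand)
  env <- environment(f)
  list(mu = root$mu, sigma = root$g, state = env$last_state)
}

#' Chemical potential realizing a target tension
#'
#' Root-finds `mu` such that the planar bilayer tension equals
#' `sigma_target` (model units; convert a physical tension first with
#' [sigma_dyn_cm_to_model()]).
#'
#' @inheritParams find_tensionless_mu
#' @param sigma_target target tension in model units (> 0).
#' @param tol_sigma relative tolerance on the achieved tension.
#' @return A list with `mu`, `sigma` and the converged planar `state`.
#' @export
find_mu_for_tension <- function(params, grid, sigma_target, init = NULL,
                                bracket = c(10, 12), tol_sigma = 1e-3,
                                max_expand = 8, ...) {
  stopifnot(sigma_target > 0)
  f <- planar_tension_fn(params, grid, init, ...)
  root <- bisect_decreasing(function(mu) f(mu) - sigma_target,
                            bracket[1], bracket[2],
                            tol_sigma * sigma_target, max_expand)
  env <- environment(f)
  list(mu = root$mu, sigma = root$g + sigma_target,
       state = env$last_state)
}

#' Planar tension curve over a set of chemical potentials
#'
#' Converges the planar bilayer at each `mu` (warm-started sequentially)
#' and tabulates the tension.
#'
#' @inheritParams planar_tension_fn
#' @param mus chemical potentials to evaluate, in sweep order.
#' @param units optional [unit_map()] adding a `sigma_dyn_cm` column.
#' @return A data frame with `mu`, `sigma` and optionally `sigma_dyn_cm`.
#' @export
tension_curve <- function(mus, params, grid, init = NULL, units = NULL,
                          ...) {
  f <- planar_tension_fn(params, grid, init, ...)
  sig <- vapply(mus, f, numeric(1))
  out <- data.frame(mu = mus, sigma = sig)
  if (!is.null(units)) out$sigma_dyn_cm <- sigma_model_to_dyn_cm(sig, units)
  out
}
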
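#' Model parameters of the lipid/solvent Gaussian-chain mixture
#'
#' Defines the standard amphiphile model used throughout the package: the
#' lipid is an AB diblock copolymer of `N` segments, a tail (A) block of
#' fraction `f` and a head (B) block of fraction `1 - f`; the solvent is a
#' short B-type homopolymer of `solvent_ratio * N` segments.  Segment
#' incompatibility is `chiN` (Flory-Huggins chi times N).  Lengths are
#' measured in units of the natural lipid end-to-end distance
#' `R0 = b * sqrt(N)` and the contour variable `s` runs over `[0, 1]` for the
#' lipid.  Calculations are semi-grand canonical: the overall segment density
#' is fixed and lipid and solvent are exchanged with a reservoir at exchange
#' chemical potential `mu = mu_lipid - mu_solvent` (in kT; the solvent
#' activity is fixed to 1 by convention, so `mu` multiplies only the lipid
#' Boltzmann weight).
#'
#' @param chiN A-B repulsion times lipid chain length (dimensionless).
#' @param f lipid tail (A-block) fraction, in (0, 1).
#' @param solvent_ratio solvent chain length over lipid chain length, > 0.
#' @param mu exchange chemical potential of lipid vs solvent, in kT.
#' @param ds contour step as a fraction of the lipid chain.  `f/ds` and
#'   `(1-f)/ds` must be integers so the tail/head junction falls on a contour
#'   grid point.
#' @param kappa_incomp strength of the incompressibility drive used inside
#'   the fixed-point iteration.  The constraint is enforced exactly at the
#'   fixed point via the pressure field; this coefficient only sets how hard
#'   local density excess is pushed back during iteration.
#'
#' @return An object of class `scft_params`.
#' @examples
#' p <- scft_params(mu = 20)
#' p$chiN
#' @export
scft_params <- function(chiN = 30, f = 0.8, solvent_ratio = 0.1, mu = 0,
                        ds = 0.01, kappa_incomp = 30) {
  stopifnot(is.numeric(chiN), length(chiN) == 1L, is.finite(chiN), chiN > 0)
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f < 1)
  stopifnot(is.numeric(solvent_ratio), length(solvent_ratio) == 1L,
            solvent_ratio > 0)
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  stopifnot(is.numeric(ds), length(ds) == 1L, ds > 0)
  stopifnot(is.numeric(kappa_incomp), length(kappa_incomp) == 1L,
            kappa_incomp >= 0)

  n_tail <- f / ds
  n_head <- (1 - f) / ds
  n_solv <- solvent_ratio / ds
  if (abs(n_tail - round(n_tail)) > 1e-8 || abs(n_head - round(n_head)) > 1e-8)
    stop("f/ds and (1-f)/ds must be integers (junction on a contour point)")
  if (abs(n_solv - round(n_solv)) > 1e-8)
    stop("solvent_ratio/ds must be an integer number of contour steps")

  structure(list(chiN = chiN, f = f, solvent_ratio = solvent_ratio, mu = mu,
                 ds = ds, kappa_incomp = kappa_incomp,
                 n_tail = as.integer(round(n_tail)),
                 n_head = as.integer(round(n_head)),
                 n_solv = as.integer(round(n_solv))),
            class = "scft_params")
}

#' @export
print.scft_params <- function(x, ...) {
  cat("SCFT model parameters (lipid = AB diblock, solvent = short B chain)\n")
  cat(sprintf("  chiN = %g   f = %g   N_s/N = %g\n", x$chiN, x$f,
              x$solvent_ratio))
  cat(sprintf("  mu = %g kT   ds = %g (tail %d + head %d steps, solvent %d)\n",
              x$mu, x$ds, x$n_tail, x$n_head, x$n_solv))
  invisible(x)
}

#' Replace the exchange chemical potential of a parameter set
#'
#' Convenience for tension sweeps: returns a copy of `params` with `mu` set.
#'
#' @param params an [scft_params()] object.
#' @param mu new exchange chemical potential (kT).
#' @return An `scft_params` object.
#' @export
set_mu <- function(params, mu) {
  stopifnot(inherits(params, "scft_params"), is.finite(mu))
  params$mu <- mu
  params
}
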
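# Closed-form thermodynamics of the spatially homogeneous mixture.
#
# For uniform composition the SCFT equations collapse to Flory-Huggins
# theory of the lipid/solvent mixture.  With lipid volume fraction phi_l
# (tail fraction f of it is A) and solvent fraction phi_s = 1 - phi_l, the
# grand-potential density (kT per chain-scale volume rho R0^3 / N, solvent
# activity 1) is
#   omega(phi_l) = phi_l (ln phi_l - 1)
#                + (phi_s / alpha) (ln phi_s - 1)
#                + chiN f phi_l (1 - f phi_l) - mu phi_l,
# and stationarity d omega / d phi_l = 0 gives the chemical potential of a
# uniform state of composition phi_l:
#   mu(phi_l) = ln phi_l - (1/alpha) ln(1 - phi_l) + f chiN (1 - 2 f phi_l).
# These closed forms serve as independent oracles for the field-theoretic
# solver and provide the bulk reference entering tension and excess free
# energies.

#' Chemical potential of a homogeneous mixture of given lipid fraction
#'
#' @param phi_l lipid volume fraction, in (0, 1) (vectorized).
#' @param params an [scft_params()] object (`mu` is ignored here).
#' @return `mu` (kT) at which a uniform state of composition `phi_l` is
#'   stationary.
#' @export
homogeneous_mu <- function(phi_l, params) {
  stopifnot(inherits(params, "scft_params"))
  a <- params$solvent_ratio; f <- params$f; chiN <- params$chiN
  log(phi_l) - log(1 - phi_l) / a + f * chiN * (1 - 2 * f * phi_l)
}

#' Flory-Huggins grand-potential density of a homogeneous mixture
#'
#' @inheritParams homogeneous_mu
#' @param mu exchange chemical potential (kT); defaults to `params$mu`.
#' @return Grand-potential density in kT per `rho R0^3 / N` volume.
#' @export
homogeneous_grand_density <- function(phi_l, params, mu = params$mu) {
  stopifnot(inherits(params, "scft_params"))
  a <- params$solvent_ratio; f <- params$f; chiN <- params$chiN
  phi_s <- 1 - phi_l
  phi_l * (log(phi_l) - 1) + phi_s / a * (log(phi_s) - 1) +
    chiN * f * phi_l * (1 - f * phi_l) - mu * phi_l
}

#' Solve the homogeneous mixture at fixed exchange chemical potential
#'
#' Inverts `mu(phi_l)` by bisection on the requested branch.  Below the
#' self-assembly regime `mu(phi_l)` is monotone and the solution is unique;
#' inside it the curve is S-shaped and the `"solvent"` branch (dilute lipid,
#' the bulk reservoir state) and the `"lipid"` branch (concentrated) are
#' distinguished by bracketing up to / down from the interior turning
#' points.
#'
#' @param params an [scft_params()] object whose `mu` is the target.
#' @param branch `"solvent"` (default) or `"lipid"`.
#' @param tol bisection tolerance on `phi_l`.
#' @return A list with `phi_l`, `phi_tail`, `phi_head`, `phi_solvent`,
#'   `omega` (grand-potential density) and the uniform propagation fields
#'   `W_A`, `W_B` and pressure `xi` of the corresponding SCFT solution.
#' @export
solve_homogeneous <- function(params, branch = c("solvent", "lipid"),
                              tol = 1e-14) {
  branch <- match.arg(branch)
  mu <- params$mu
  eps <- 1e-300
  # locate turning points of mu(phi) on a fine grid
  phis <- seq(1e-8, 1 - 1e-8, length.out = 20001)
  mus <- homogeneous_mu(phis, params)
  dmu <- diff(mus)
  turn <- which(diff(sign(dmu)) != 0)
  if (branch == "solvent") {
    hi <- if (length(turn)) phis[turn[1] + 1] else 1 - 1e-12
    if (homogeneous_mu(hi, params) < mu)
      stop("mu above the solvent-branch range (no dilute solution)")
    lo <- eps
  } else {
    lo <- if (length(turn)) phis[turn[length(turn)] + 1] else 1e-12
    hi <- 1 - 1e-15
    if (homogeneous_mu(lo, params) > mu)
      stop("mu below the lipid-branch range (no concentrated solution)")
  }
  g <- function(p) homogeneous_mu(p, params) - mu
  # bisection (mu is increasing on both outer branches)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * mid) break
  }
  phi_l <- (lo + hi) / 2
  phi_s <- 1 - phi_l
  f <- params$f; chiN <- params$chiN; a <- params$solvent_ratio
  W_B <- -log(phi_s) / a
  xi <- W_B - chiN * f * phi_l
  W_A <- chiN * (1 - f * phi_l) + xi
  list(phi_l = phi_l, phi_tail = f * phi_l, phi_head = (1 - f) * phi_l,
       phi_solvent = phi_s,
       omega = homogeneous_grand_density(phi_l, params),
       W_A = W_A, W_B = W_B, xi = xi)
}
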
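#' Semi-grand canonical free energy of a field/density pair
#'
#' Evaluates the grand-potential functional (in kT per `rho R0^3 / N`
#' volume scale)
#' \deqn{\Omega = -e^{\mu} V Q_l - \frac{1}{\alpha} V Q_s +
#'   \int \left[\chi N \phi_A \phi_B - W_A \phi_A - W_B \phi_B\right] dV,}
#' where `phi_A = phi_tail`, `phi_B = phi_head + phi_solvent` and
#' `W = w + xi` are the total propagation fields.  The single-chain
#' partition terms are evaluated through the exact identities
#' `e^mu V Q_l = int (phi_tail + phi_head) dV` and
#' `V Q_s = int phi_solvent dV`, so the functional is purely algebraic in
#' the given pair and manifestly invariant under the `(w + c, xi - c)`
#' gauge.  In the homogeneous limit it reduces to the Flory-Huggins grand
#' potential of [homogeneous_grand_density()].
#'
#' @param fields an [field_state()] object.
#' @param dens the [density_state()] computed from `fields`.
#' @param params an [scft_params()] object.
#' @param grid an [make_grid()] object.
#' @return Scalar free energy (kT; extensive over the grid volume, per unit
#'   cross-section area for `planar1d` and per unit length for `radial1d`).
#' @seealso [excess_free_energy()] for the value relative to bulk solvent.
#' @export
grand_free_energy <- function(fields, dens, params, grid) {
  stopifnot(inherits(fields, "scft_fields"), inherits(dens, "scft_density"))
  W <- prop_fields(fields)
  phi_A <- dens$phi_tail
  phi_B <- dens$phi_head + dens$phi_solvent
  lipid_term <- integrate_field(dens$phi_tail + dens$phi_head, grid)
  solv_term <- integrate_field(dens$phi_solvent, grid) / params$solvent_ratio
  inter <- integrate_field(params$chiN * phi_A * phi_B -
                           W$W_A * phi_A - W$W_B * phi_B, grid)
  -lipid_term - solv_term + inter
}

#' Excess free energy relative to homogeneous bulk solvent
#'
#' Subtracts `V * omega_bulk(mu)`, the grand potential the same volume
#' would have if filled with the dilute (solvent-branch) homogeneous
#' mixture at the same exchange chemical potential.  For a converged planar
#' bilayer this is the tension times area; for a tube, the excess energy
#' per unit length.
#'
#' @inheritParams grand_free_energy
#' @return Scalar excess free energy (kT).
#' @export
excess_free_energy <- function(fields, dens, params, grid) {
  omega_b <- solve_homogeneous(params, "solvent")$omega
  grand_free_energy(fields, dens, params, grid) - omega_b * grid$volume
}
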
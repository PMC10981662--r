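#' Calibration between model units and physical units
#'
#' SCFT results come out in model units: lengths in R0 (the lipid
#' end-to-end distance) and free energies in kT per `rho R0^3 / N`, i.e.
#' per unit dimensionless chain density `C = rho R0^3 / N`.  Two anchors
#' map them to physical units:
#' \itemize{
#'   \item `nm_per_R0` - set by matching the tensionless bilayer thickness
#'     to a physical thickness (5 nm by default, the standard fluid
#'     phosphatidylcholine value, see [calibrate_units()]).
#'   \item `chain_density` (`C`) - the number of lipid-chain volumes per
#'     R0^3, which converts model free energies to kT.  By default it is
#'     anchored to the molecular volume of POPC (1.26 nm^3):
#'     `C = nm_per_R0^3 / lipid_volume_nm3`.
#' }
#' With `kBT_J = 4.11e-21` J (298 K), 1 kT/nm^2 = 4.11 mN/m = 4.11 Dyn/cm,
#' so a tension `sigma` in kT/R0^2 equals
#' `sigma * 4.11 / nm_per_R0^2` Dyn/cm.
#'
#' @param nm_per_R0 physical length of one R0, in nm (> 0).
#' @param kBT_J thermal energy in joule (default 4.11e-21, 298 K).
#' @param chain_density dimensionless chain density `C`; computed from
#'   `lipid_volume_nm3` when `NULL`.
#' @param lipid_volume_nm3 molecular volume anchoring `C` (default 1.26,
#'   POPC).
#' @return An object of class `unit_map`.
#' @export
unit_map <- function(nm_per_R0, kBT_J = 4.11e-21, chain_density = NULL,
                     lipid_volume_nm3 = 1.26) {
  stopifnot(nm_per_R0 > 0, kBT_J > 0, lipid_volume_nm3 > 0)
  C <- if (is.null(chain_density)) nm_per_R0^3 / lipid_volume_nm3 else
    chain_density
  stopifnot(C > 0)
  structure(list(nm_per_R0 = nm_per_R0, kBT_J = kBT_J, chain_density = C,
                 kBT_per_nm2_dyn_cm = kBT_J * 1e21),
            class = "unit_map")
}

#' @export
print.unit_map <- function(x, ...) {
  cat(sprintf(
    "Unit map: 1 R0 = %.4g nm, C = %.4g chains/R0^3, 1 kT/nm^2 = %.4g Dyn/cm\n",
    x$nm_per_R0, x$chain_density, x$kBT_per_nm2_dyn_cm))
  invisible(x)
}

#' Convert tensions between kT/R0^2 and Dyn/cm
#'
#' @param sigma tension in kT/R0^2 (resp. Dyn/cm for the inverse).
#' @param units an [unit_map()].
#' @return Converted tension.
#' @export
sigma_kBT_to_dyn_cm <- function(sigma, units) {
  stopifnot(inherits(units, "unit_map"))
  sigma * units$kBT_per_nm2_dyn_cm / units$nm_per_R0^2
}

#' @rdname sigma_kBT_to_dyn_cm
#' @export
sigma_dyn_cm_to_kBT <- function(sigma, units) {
  stopifnot(inherits(units, "unit_map"))
  sigma * units$nm_per_R0^2 / units$kBT_per_nm2_dyn_cm
}

#' Convert raw model tensions / rigidities to thermal units
#'
#' Raw SCFT free energies are per unit chain density; multiplying by `C`
#' expresses them in kT.
#'
#' @param x raw model value (tension in model units for
#'   `sigma_model_to_dyn_cm`; rigidity for `kappa_model_to_kBT`).
#' @param units an [unit_map()].
#' @return Converted value.
#' @export
sigma_model_to_dyn_cm <- function(x, units) {
  sigma_kBT_to_dyn_cm(x * units$chain_density, units)
}

#' @rdname sigma_model_to_dyn_cm
#' @export
sigma_dyn_cm_to_model <- function(x, units) {
  sigma_dyn_cm_to_kBT(x, units) / units$chain_density
}

#' @rdname sigma_model_to_dyn_cm
#' @export
kappa_model_to_kBT <- function(x, units) {
  stopifnot(inherits(units, "unit_map"))
  x * units$chain_density
}

#' Calibrate physical units from a tensionless planar bilayer
#'
#' Sets the length scale by equating the computed head peak-to-peak
#' bilayer thickness with a physical thickness (5 nm by default) and
#' anchors the energy scale through the lipid molecular volume.
#'
#' @param planar_state a converged tensionless `scft_state` on `planar1d`.
#' @param target_thickness_nm physical thickness assigned to the computed
#'   bilayer (default 5 nm).
#' @inheritParams unit_map
#' @return An [unit_map()]; the model thickness (R0) is attached as
#'   attribute `"thickness_R0"`.
#' @export
calibrate_units <- function(planar_state, target_thickness_nm = 5,
                            kBT_J = 4.11e-21, lipid_volume_nm3 = 1.26) {
  geo <- bilayer_geometry(membrane_profile(planar_state))
  um <- unit_map(target_thickness_nm / geo$thickness, kBT_J = kBT_J,
                 lipid_volume_nm3 = lipid_volume_nm3)
  attr(um, "thickness_R0") <- geo$thickness
  um
}
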
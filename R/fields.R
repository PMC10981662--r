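#' Conjugate potential fields of an SCFT state
#'
#' Container for the fields conjugate to the tail (A) and head/solvent (B)
#' segment densities, plus the pressure-like field `xi` that enforces
#' incompressibility.  The chain propagators see the total fields
#' `W_A = w_A + xi` and `W_B = w_B + xi` (in kT per chain contour), so the
#' split between `w` and `xi` carries a gauge freedom: shifting both `w`
#' fields by a constant `c` while shifting `xi` by `-c` leaves every
#' observable unchanged.
#'
#' @param w_A,w_B numeric fields on `grid` (kT per chain), conjugate to the
#'   tail and head/solvent densities.
#' @param xi pressure field enforcing incompressibility (scalar or field).
#' @param grid an [make_grid()] object.
#' @return An object of class `scft_fields`.
#' @export
field_state <- function(w_A, w_B, xi = 0, grid) {
  stopifnot(inherits(grid, "scft_grid"))
  w_A <- as.numeric(w_A); w_B <- as.numeric(w_B); xi <- as.numeric(xi)
  if (length(w_A) == 1L) w_A <- rep(w_A, grid$npts)
  if (length(w_B) == 1L) w_B <- rep(w_B, grid$npts)
  if (length(xi) == 1L) xi <- rep(xi, grid$npts)
  if (length(w_A) != grid$npts || length(w_B) != grid$npts ||
      length(xi) != grid$npts)
    stop("field shape does not match grid")
  if (!all(is.finite(w_A)) || !all(is.finite(w_B)) || !all(is.finite(xi)))
    stop("non-finite field values")
  structure(list(w_A = w_A, w_B = w_B, xi = xi, grid = grid),
            class = "scft_fields")
}

# total fields seen by the propagators
prop_fields <- function(fields) {
  list(W_A = fields$w_A + fields$xi, W_B = fields$w_B + fields$xi)
}

#' Species volume fractions of an SCFT state
#'
#' @param phi_tail,phi_head,phi_solvent local volume fractions on `grid`
#'   (lipid tail, lipid head, solvent).
#' @param grid an [make_grid()] object.
#' @return An object of class `scft_density`.
#' @export
density_state <- function(phi_tail, phi_head, phi_solvent, grid) {
  stopifnot(inherits(grid, "scft_grid"))
  n <- grid$npts
  if (length(phi_tail) != n || length(phi_head) != n ||
      length(phi_solvent) != n)
    stop("density shape does not match grid")
  structure(list(phi_tail = as.numeric(phi_tail),
                 phi_head = as.numeric(phi_head),
                 phi_solvent = as.numeric(phi_solvent), grid = grid),
            class = "scft_density")
}

#' @export
print.scft_density <- function(x, ...) {
  inc <- max(abs(x$phi_tail + x$phi_head + x$phi_solvent - 1))
  cat(sprintf(
    "SCFT densities on %s grid (n = %d): max phi_tail = %.3f, |sum-1| = %.2e\n",
    x$grid$kind, x$grid$npts, max(x$phi_tail), inc))
  invisible(x)
}

# densities stacked as an npts x 3 matrix (tail, head, solvent)
density_matrix <- function(dens) {
  cbind(dens$phi_tail, dens$phi_head, dens$phi_solvent)
}
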
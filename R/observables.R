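#' Species profile along the membrane normal or radius
#'
#' Extracts the 1D volume-fraction profiles from a converged planar or
#' radial SCFT state (or from a density state plus grid).
#'
#' @param x an `scft_state` from [scft_converge()] or an
#'   [density_state()].
#' @param grid required when `x` is a density state.
#' @return An object of class `membrane_profile` with `coord`, `phi_tail`,
#'   `phi_head`, `phi_solvent` and the coordinate label.
#' @export
membrane_profile <- function(x, grid = NULL) {
  if (inherits(x, "scft_state")) { grid <- x$grid; x <- x$dens }
  stopifnot(inherits(x, "scft_density"), inherits(grid, "scft_grid"))
  if (!grid$kind %in% c("planar1d", "radial1d"))
    stop("membrane_profile expects a planar1d or radial1d state")
  structure(list(coord = grid$coords[[1]], phi_tail = x$phi_tail,
                 phi_head = x$phi_head, phi_solvent = x$phi_solvent,
                 axis = names(grid$coords)[1]),
            class = "membrane_profile")
}

# quadratic (three-point) interpolation of a discrete peak position
peak_interp <- function(xv, yv, i) {
  n <- length(xv)
  if (i <= 1L || i >= n) return(xv[i])
  denom <- yv[i - 1] - 2 * yv[i] + yv[i + 1]
  if (abs(denom) < .Machine$double.eps) return(xv[i])
  delta <- 0.5 * (yv[i - 1] - yv[i + 1]) / denom
  xv[i] + delta * (xv[2] - xv[1])
}

# contiguous index runs where the tail fraction exceeds half its maximum;
# a genuine hydrophobic core must also be tail-majority in absolute terms
tail_cores <- function(phi_tail, frac = 0.5) {
  thr <- max(frac * max(phi_tail), 0.25)
  above <- phi_tail > thr
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) starts[k]:ends[k])
}

#' Bilayer thickness and midplane position from a profile
#'
#' Thickness follows the head peak-to-peak convention (the distance between
#' the two head-density maxima flanking the tail core, the analogue of the
#' dark-band separation measured on cryoEM micrographs); the midplane is
#' the center of mass of the tail core.  Both are sub-grid accurate via
#' quadratic peak interpolation.  The hydrophobic-core full width at half
#' maximum is returned as a secondary diagnostic.
#'
#' @param profile an [membrane_profile()] containing exactly one bilayer.
#' @return A list with `thickness`, `midplane`, `head_peaks` (positions of
#'   the flanking head maxima), `core_fwhm` (all in R0).
#' @export
bilayer_geometry <- function(profile) {
  stopifnot(inherits(profile, "membrane_profile"))
  cores <- tail_cores(profile$phi_tail)
  if (length(cores) == 0L) stop("no bilayer core found in profile")
  if (length(cores) > 1L)
    stop("multiple bilayer cores found; window the profile first")
  core_geometry(profile, cores[[1]], 1L, length(profile$coord))
}

# geometry of one tail core, searching head peaks within [lo, hi]
core_geometry <- function(profile, run, lo, hi) {
  xv <- profile$coord; pt <- profile$phi_tail; ph <- profile$phi_head
  midplane <- sum(xv[run] * pt[run]) / sum(pt[run])
  i0 <- run[1]; i1 <- run[length(run)]
  left_rng <- lo:i0
  right_rng <- i1:hi
  il <- left_rng[which.max(ph[left_rng])]
  ir <- right_rng[which.max(ph[right_rng])]
  xl <- peak_interp(xv, ph, il)
  xr <- peak_interp(xv, ph, ir)

  # tail-core FWHM by linear interpolation of the half-max crossings
  half <- max(pt[run]) / 2
  cross <- function(i, j) {
    if (pt[j] == pt[i]) return(xv[i])
    xv[i] + (half - pt[i]) * (xv[j] - xv[i]) / (pt[j] - pt[i])
  }
  fl <- if (i0 > lo) cross(i0 - 1L, i0) else xv[i0]
  fr <- if (i1 < hi) cross(i1 + 1L, i1) else xv[i1]

  list(thickness = xr - xl, midplane = midplane, head_peaks = c(xl, xr),
       core_fwhm = abs(fr - fl))
}

#' Membrane tension of a converged planar bilayer
#'
#' The tension is the excess grand free energy per unit membrane area of
#' the planar state relative to homogeneous bulk solvent at the same
#' exchange chemical potential; in `planar1d` the free energies are already
#' per unit cross-sectional area.
#'
#' @param state a converged `scft_state` on a `planar1d` grid.
#' @param units optional [unit_map()]; when given, `sigma_phys` (Dyn/cm) is
#'   included.
#' @return An object of class `tension_point`: `mu`, `sigma` (kT per R0^2
#'   at unit chain density) and optionally `sigma_phys`.
#' @export
tension <- function(state, units = NULL) {
  stopifnot(inherits(state, "scft_state"))
  if (state$grid$kind != "planar1d")
    stop("tension expects a planar1d state")
  if (!isTRUE(state$converged)) stop("tension of a non-converged state")
  sig <- state$excess_free_energy   # area = 1 in planar1d
  structure(list(mu = state$params$mu, sigma = sig,
                 sigma_phys = if (!is.null(units))
                   sigma_model_to_dyn_cm(sig, units)),
            class = "tension_point")
}

#' Midplane radius (or radii) of a converged membrane tube
#'
#' Applies the bilayer-geometry conventions along the radial coordinate of
#' a cylindrical state: a single-membrane tube yields one midplane radius,
#' a double-membrane tube two (inner, outer).  The midplane-radius
#' convention matches the fluorometry definition (distance from the tube
#' center to the middle of the bilayer).
#'
#' @param state a converged `scft_state` on a `radial1d` grid.
#' @param n_membranes expected number of nested bilayers (`NULL` accepts
#'   what is found).
#' @return A list with `radii` (sorted, R0), `thickness` per membrane, and
#'   the per-membrane geometry details.
#' @export
tube_radius <- function(state, n_membranes = NULL) {
  stopifnot(inherits(state, "scft_state"))
  if (state$grid$kind != "radial1d")
    stop("tube_radius expects a radial1d state")
  prof <- membrane_profile(state)
  cores <- tail_cores(prof$phi_tail)
  if (!is.null(n_membranes) && length(cores) != n_membranes)
    stop(sprintf("expected %d bilayer core(s), found %d", n_membranes,
                 length(cores)))
  if (length(cores) == 0L) stop("no bilayer core found")
  n <- length(prof$coord)
  bounds <- c(1L, vapply(seq_len(length(cores) - 1L), function(k) {
    a <- cores[[k]][length(cores[[k]])]; b <- cores[[k + 1L]][1L]
    as.integer((a + b) %/% 2)
  }, integer(1)), n)
  geo <- lapply(seq_along(cores), function(k)
    core_geometry(prof, cores[[k]], bounds[k], bounds[k + 1L]))
  radii <- vapply(geo, `[[`, numeric(1), "midplane")
  ord <- order(radii)
  list(radii = radii[ord],
       thickness = vapply(geo, `[[`, numeric(1), "thickness")[ord],
       details = geo[ord])
}

#' Fit the bending rigidity from a tube radius-tension relation
#'
#' Least-squares fit of the Helfrich tube law `r = sqrt(kappa / (2 sigma))`
#' to `(radius, sigma)` points, with the log-log slope of `r` vs `sigma`
#' returned as a diagnostic of how well the inverse-square-root law holds
#' (ideal value -1/2).
#'
#' @param radius,sigma numeric vectors (same units convention; `kappa`
#'   comes out in `sigma * radius^2` units).  At least 3 points spanning a
#'   factor >= 2 in `sigma` are required.
#' @return A list with `kappa`, `exponent`, and `fitted` radii.
#' @export
fit_kappa <- function(radius, sigma) {
  stopifnot(length(radius) == length(sigma), length(radius) >= 3,
            all(radius > 0), all(sigma > 0))
  if (max(sigma) / min(sigma) < 2)
    stop("degenerate spread: sigma values must span at least a factor of 2")
  y <- 1 / sqrt(2 * sigma)
  sqrt_kappa <- sum(radius * y) / sum(y^2)
  expo <- unname(stats::coef(stats::lm(log(radius) ~ log(sigma)))[2])
  list(kappa = sqrt_kappa^2, exponent = expo, fitted = sqrt_kappa * y)
}

#' Radius of a membrane tube at given rigidity and tension
#'
#' The mechanical equilibrium radius of a tether pulled from a reservoir
#' at tension `sigma` with bending rigidity `kappa`:
#' `r = sqrt(kappa / (2 sigma))`.  Units must be consistent (e.g. `kappa`
#' in J and `sigma` in J/m^2 gives r in m; `kappa` in kT and `sigma` in
#' kT/nm^2 gives nm).
#'
#' @param kappa bending rigidity (> 0).
#' @param sigma membrane tension (> 0).
#' @return Tube radius.
#' @export
radius_from_tension <- function(kappa, sigma) {
  if (any(kappa <= 0)) stop("kappa must be positive")
  if (any(sigma <= 0)) stop("sigma must be positive")
  sqrt(kappa / (2 * sigma))
}
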
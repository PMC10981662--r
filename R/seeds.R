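#' Build seed fields for membrane topologies
#'
#' Constructs tanh-interface tail-density ansaetze for the membrane
#' configurations used as SCFT initializations and string endpoints, and
#' converts them to seed fields (`w_A = chiN (1 - t)`, `w_B = chiN t`,
#' `xi = 0`, where `t` is the smoothed tail-core indicator).  Supported
#' kinds and their geometry arguments (all lengths in R0):
#' \describe{
#'   \item{`planar_bilayer`}{`center` (default mid-box), `half_core`.}
#'   \item{`sm_tube`}{`r0` midplane radius; radial or axisymmetric grid.}
#'   \item{`dm_tube`}{`r_in` inner midplane radius, `gap` head-to-head
#'     water gap, `thickness` bilayer thickness; the outer midplane sits at
#'     `r_in + thickness + gap` by construction.}
#'   \item{`stalk`}{two bilayers at midplane separation `separation`
#'     centered on `center_z`, connected by an axial neck of radius
#'     `neck_radius` (axisymmetric grid).}
#'   \item{`pore`}{planar bilayer at `center_z` with an axial pore of
#'     radius `pore_radius` (axisymmetric grid).}
#'   \item{`wlm_bridge`}{worm-like micelle: cylindrical tail-core capsule of
#'     radius `core_radius` and length `length` along the axis.}
#'   \item{`capped_tube`}{tube of radius `r0` closed by a hemispherical cap
#'     at `cap_z` (axisymmetric grid).}
#' }
#'
#' @param kind topology name (see Details).
#' @param grid an [make_grid()] object of a compatible geometry.
#' @param params an [scft_params()] object (supplies `chiN`).
#' @param ... geometry arguments listed above.
#' @param half_core half-width of the tail core slab/shell (default 0.65).
#' @param width tanh interface width (default 0.3).
#' @return An [field_state()] seed; the smoothed tail indicator is attached
#'   as attribute `"phi_tail"`.
#' @export
seed_topology <- function(kind = c("planar_bilayer", "sm_tube", "dm_tube",
                                   "stalk", "pore", "wlm_bridge",
                                   "capped_tube"),
                          grid, params, ..., half_core = 0.65, width = 0.3) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "scft_grid"), inherits(params, "scft_params"))
  args <- list(...)
  st <- function(d) 0.5 * (1 + tanh(2 * d / width))
  t_core <- half_core

  coords2d <- function() {
    if (grid$kind != "axisym2d")
      stop(sprintf("'%s' seed requires an axisym2d grid", kind))
    list(R = rep(grid$coords$r, times = grid$dims[2]),
         Z = rep(grid$coords$z, each = grid$dims[1]))
  }
  radial_coord <- function() {
    if (grid$kind == "radial1d") return(grid$coords$r)
    if (grid$kind == "axisym2d") return(coords2d()$R)
    stop(sprintf("'%s' seed requires a radial or axisymmetric grid", kind))
  }

  d <- switch(kind,
    planar_bilayer = {
      if (grid$kind != "planar1d")
        stop("'planar_bilayer' seed requires a planar1d grid")
      center <- args$center %||% (grid$extent / 2)
      t_core - abs(grid$coords$x - center)
    },
    sm_tube = {
      r0 <- args$r0 %||% stop("sm_tube seed requires 'r0'")
      if (r0 <= t_core) stop("sm_tube: r0 must exceed the core half-width")
      t_core - abs(radial_coord() - r0)
    },
    dm_tube = {
      r_in <- args$r_in %||% stop("dm_tube seed requires 'r_in'")
      gap <- args$gap %||% stop("dm_tube seed requires 'gap'")
      thickness <- args$thickness %||% 1.8
      if (gap < 0) stop("dm_tube: gap must be non-negative")
      if (r_in <= t_core) stop("dm_tube: r_in must exceed the core half-width")
      r_out <- r_in + thickness + gap
      if (r_out > max(radial_coord()))
        stop("dm_tube: outer tube does not fit inside the grid")
      r <- radial_coord()
      pmax(t_core - abs(r - r_in), t_core - abs(r - r_out))
    },
    stalk = {
      cc <- coords2d()
      sep <- args$separation %||% stop("stalk seed requires 'separation'")
      neck <- args$neck_radius %||% 1
      zc <- args$center_z %||% (grid$extent[2] / 2)
      if (sep <= 2 * t_core)
        stop("stalk: separation must exceed the core thickness (overlap)")
      d1 <- t_core - abs(cc$Z - (zc - sep / 2))
      d2 <- t_core - abs(cc$Z - (zc + sep / 2))
      d3 <- pmin(neck - cc$R, sep / 2 + t_core - abs(cc$Z - zc))
      pmax(d1, d2, d3)
    },
    pore = {
      cc <- coords2d()
      rp <- args$pore_radius %||% stop("pore seed requires 'pore_radius'")
      zc <- args$center_z %||% (grid$extent[2] / 2)
      if (rp <= 0) stop("pore: pore_radius must be positive")
      pmin(t_core - abs(cc$Z - zc), cc$R - rp)
    },
    wlm_bridge = {
      cc <- coords2d()
      len <- args$length %||% stop("wlm_bridge seed requires 'length'")
      a <- args$core_radius %||% 0.55
      zc <- args$center_z %||% (grid$extent[2] / 2)
      dz <- pmax(abs(cc$Z - zc) - len / 2, 0)
      a - sqrt(cc$R^2 + dz^2)   # capsule distance to the axis segment
    },
    capped_tube = {
      cc <- coords2d()
      r0 <- args$r0 %||% stop("capped_tube seed requires 'r0'")
      cap_z <- args$cap_z %||% (grid$extent[2] / 2)
      if (r0 <= t_core) stop("capped_tube: r0 must exceed the core half-width")
      mid <- ifelse(cc$Z <= cap_z, abs(cc$R - r0),
                    abs(sqrt(cc$R^2 + (cc$Z - cap_z)^2) - r0))
      t_core - mid
    })

  phi <- st(d)
  fs <- field_state(params$chiN * (1 - phi), params$chiN * phi, 0, grid)
  attr(fs, "phi_tail") <- phi
  fs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
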
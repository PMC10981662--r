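#' Chain propagators in given fields
#'
#' Integrates the modified diffusion equation
#' `dq/ds = (1/6) lap(q) - W(r) q` (lengths in R0) for the lipid forward
#' propagator `q` (tail end first: field `W_A` for `s < f`, `W_B` after),
#' the lipid backward propagator `qdag` (head end first), and the solvent
#' propagator `qs` (`W_B` over `s` in `[0, solvent_ratio]`), all from the
#' free initial condition `q = 1`.  Contour stepping is symmetric operator
#' splitting (half field, full diffusion, half field), second order in `ds`
#' and unconditionally stable.
#'
#' @param fields an [field_state()] object (the propagators see
#'   `w + xi`).
#' @param grid an [make_grid()] object.
#' @param params an [scft_params()] object.
#' @return An object of class `scft_propagators`: matrices `q`, `qdag`
#'   (`npts x (n_s_steps+1)`) and `qs`, plus the contour bookkeeping.
#' @export
propagate <- function(fields, grid, params) {
  stopifnot(inherits(fields, "scft_fields"), inherits(grid, "scft_grid"),
            inherits(params, "scft_params"))
  if (length(fields$w_A) != grid$npts)
    stop("field shape does not match grid")
  W <- prop_fields(fields)
  ds <- params$ds
  n_tail <- params$n_tail; n_head <- params$n_head; n_solv <- params$n_solv
  ntot <- n_tail + n_head

  expA <- exp(-W$W_A * ds / 2)
  expB <- exp(-W$W_B * ds / 2)

  fd1d <- grid$kind == "radial1d" ||
    (grid$kind == "planar1d" && grid$boundary != "periodic")

  if (fd1d) {
    # finite-difference 1D: full contour loop in compiled code
    b <- lap_bands(grid$dims[1], grid$spacing[1],
                   radial = grid$kind == "radial1d")
    th <- ds / 12
    q <- cpp_prop_1d(b$lo, b$d, b$up, th, expA, expB, n_tail, ntot)
    qdag <- cpp_prop_1d(b$lo, b$d, b$up, th, expB, expA, n_head, ntot)
    qs <- cpp_prop_1d(b$lo, b$d, b$up, th, expB, expB, n_solv, n_solv)
  } else if (grid$kind == "axisym2d") {
    br <- lap_bands(grid$dims[1], grid$spacing[1], radial = TRUE)
    bz <- lap_bands(grid$dims[2], grid$spacing[2], radial = FALSE)
    thr <- ds / 12; thz <- ds / 24
    q <- cpp_prop_2d(br$lo, br$d, br$up, bz$lo, bz$d, bz$up, thr, thz,
                     expA, expB, n_tail, ntot, grid$dims[1], grid$dims[2])
    qdag <- cpp_prop_2d(br$lo, br$d, br$up, bz$lo, bz$d, bz$up, thr, thz,
                        expB, expA, n_head, ntot, grid$dims[1],
                        grid$dims[2])
    qs <- cpp_prop_2d(br$lo, br$d, br$up, bz$lo, bz$d, bz$up, thr, thz,
                      expB, expB, n_solv, n_solv, grid$dims[1],
                      grid$dims[2])
  } else {
    # spectral geometries: diffusion substep exact in Fourier space.
    # The exact propagator is strictly positive; clamp the tiny negative
    # undershoots of spectral ringing in regions of deep decay.
    D <- make_diffusion_op(grid, ds)
    step <- function(v, e) pmax(e * D(e * v), 0)
    q <- matrix(0, grid$npts, ntot + 1L)
    q[, 1L] <- 1
    for (j in seq_len(ntot)) {
      e <- if (j <= n_tail) expA else expB
      q[, j + 1L] <- step(q[, j], e)
    }
    qdag <- matrix(0, grid$npts, ntot + 1L)
    qdag[, 1L] <- 1
    for (j in seq_len(ntot)) {
      e <- if (j <= n_head) expB else expA
      qdag[, j + 1L] <- step(qdag[, j], e)
    }
    qs <- matrix(0, grid$npts, n_solv + 1L)
    qs[, 1L] <- 1
    for (j in seq_len(n_solv)) qs[, j + 1L] <- step(qs[, j], expB)
  }

  if (!all(is.finite(q)) || !all(is.finite(qdag)) || !all(is.finite(qs)))
    stop("non-finite propagator values (contour step blow-up)")

  structure(list(q = q, qdag = qdag, qs = qs, n_tail = n_tail,
                 n_head = n_head, n_solv = n_solv, ds = ds),
            class = "scft_propagators")
}

# composite Newton-Cotes weights for n equal intervals of width h:
# Simpson when n is even, Simpson + 3/8 tail when n is odd (>= 3),
# trapezoid for n = 1
quad_weights <- function(n, h) {
  if (n == 1L) return(h * c(0.5, 0.5))
  w <- numeric(n + 1L)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n + 1L] <- 1
    if (n > 2L) w[seq(3L, n - 1L, by = 2L)] <- 2
    w[seq(2L, n, by = 2L)] <- 4
    w <- w * h / 3
  } else {
    m <- n - 3L
    w1 <- c(quad_weights(m, h), numeric(3L))
    if (m == 0L) w1 <- numeric(n + 1L)
    w2 <- numeric(n + 1L)
    w2[(m + 1L):(n + 1L)] <- 3 * h / 8 * c(1, 3, 3, 1)
    w <- w1 + w2
  }
  w
}

#' Assemble species densities from propagators
#'
#' Semi-grand canonical density assembly: the lipid weight carries the
#' exchange chemical potential (`exp(mu)`), the solvent activity is 1 by
#' convention, so
#' `phi_tail = exp(mu) * int_0^f q qdag ds`,
#' `phi_head = exp(mu) * int_f^1 q qdag ds`, and
#' `phi_solvent = (1/alpha) * int_0^alpha qs qs ds` with
#' `alpha = solvent_ratio`.  Contour integrals use composite Simpson
#' quadrature with the tail/head junction on a contour grid point.
#'
#' @param props propagators from [propagate()] computed in the same fields.
#' @param fields the [field_state()] used to generate `props`.
#' @param params an [scft_params()] object.
#' @param grid an [make_grid()] object.
#' @return An [density_state()] object.
#' @export
compute_densities <- function(props, fields, params, grid) {
  stopifnot(inherits(props, "scft_propagators"),
            inherits(params, "scft_params"))
  if (props$n_tail != params$n_tail || props$n_solv != params$n_solv)
    stop("propagators and params disagree on contour discretization")
  ds <- params$ds
  n_tail <- props$n_tail; n_head <- props$n_head; n_solv <- props$n_solv
  ntot <- n_tail + n_head
  act <- exp(params$mu)

  # tail: s_j = j ds, j = 0..n_tail, pairs with qdag column (ntot - j) + 1
  jt <- 0:n_tail
  wt <- quad_weights(n_tail, ds)
  phi_tail <- act *
    as.numeric((props$q[, jt + 1L, drop = FALSE] *
                props$qdag[, ntot - jt + 1L, drop = FALSE]) %*% wt)

  jh <- n_tail:ntot
  wh <- quad_weights(n_head, ds)
  phi_head <- act *
    as.numeric((props$q[, jh + 1L, drop = FALSE] *
                props$qdag[, ntot - jh + 1L, drop = FALSE]) %*% wh)

  js <- 0:n_solv
  ws <- quad_weights(n_solv, ds)
  phi_solvent <- as.numeric((props$qs[, js + 1L, drop = FALSE] *
                             props$qs[, n_solv - js + 1L, drop = FALSE]) %*%
                            ws) / params$solvent_ratio

  if (min(phi_tail, phi_head, phi_solvent) < -1e-8)
    stop("negative density: propagator corruption")
  density_state(phi_tail, phi_head, phi_solvent, grid)
}
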
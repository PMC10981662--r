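# Diffusion substep operators for the contour stepper.
#
# The modified diffusion equation dq/ds = (1/6) lap(q) - W q is integrated
# with symmetric operator splitting: exp(-W h/2) D(h) exp(-W h/2), where
# D(h) approximates exp((h/6) lap).  D is field-independent, so it is built
# once per (grid, h): exactly (spectrally) in fully periodic geometries and
# by Crank-Nicolson in finite-difference directions; the axisymmetric
# geometry uses Strang ADI (z half-step, r full step, z half-step).  All
# variants are second-order accurate in h and unconditionally stable.

make_diffusion_op <- function(grid, h) {
  stopifnot(inherits(grid, "scft_grid"), h > 0)
  kind <- grid$kind

  if (kind == "planar1d" && grid$boundary == "periodic") {
    mult <- exp(-spectral_k2(grid$dims, grid$extent) * h / 6)
    n <- grid$dims
    return(function(v) Re(stats::fft(mult * stats::fft(v), inverse = TRUE)) / n)
  }
  if (kind == "planar1d") {
    b <- lap_bands(grid$dims, grid$spacing, radial = FALSE)
    th <- h / 12
    return(function(v)
      as.numeric(cn_solve_rows(b$lo, b$d, b$up, th, matrix(v, ncol = 1))))
  }
  if (kind == "radial1d") {
    b <- lap_bands(grid$dims, grid$spacing, radial = TRUE)
    th <- h / 12
    return(function(v)
      as.numeric(cn_solve_rows(b$lo, b$d, b$up, th, matrix(v, ncol = 1))))
  }
  if (kind == "axisym2d") {
    nr <- grid$dims[1]; nz <- grid$dims[2]
    br <- lap_bands(nr, grid$spacing[1], radial = TRUE)
    bz <- lap_bands(nz, grid$spacing[2], radial = FALSE)
    thr <- h / 12   # full step in r
    thz <- h / 24   # half steps in z
    return(function(v) {
      M <- matrix(v, nr, nz)
      M <- t(cn_solve_rows(bz$lo, bz$d, bz$up, thz, t(M)))
      M <- cn_solve_rows(br$lo, br$d, br$up, thr, M)
      M <- t(cn_solve_rows(bz$lo, bz$d, bz$up, thz, t(M)))
      as.numeric(M)
    })
  }
  # cart3d: fully periodic, spectral
  mult <- exp(-cart3d_k2(grid) * h / 6)
  npts <- grid$npts
  dims <- grid$dims
  function(v) {
    a <- array(v, dims)
    as.numeric(Re(stats::fft(mult * stats::fft(a), inverse = TRUE)) / npts)
  }
}
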
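test_that("quadrature weights integrate to the analytic domain volume", {
  g1 <- make_grid("planar1d", 64, 6.4)
  expect_equal(sum(g1$weights), 6.4, tolerance = 1e-12)
  g2 <- make_grid("radial1d", 80, 5)
  expect_equal(sum(g2$weights), pi * 25, tolerance = 1e-12)
  g3 <- make_grid("axisym2d", c(40, 30), c(4, 3))
  expect_equal(sum(g3$weights), pi * 16 * 3, tolerance = 1e-12)
  g4 <- make_grid("cart3d", c(8, 8, 8), c(2, 3, 4))
  expect_equal(sum(g4$weights), 24, tolerance = 1e-12)
})

test_that("laplacian reproduces closed forms in each geometry", {
  # constant field -> 0
  for (g in list(make_grid("planar1d", 32, 4),
                 make_grid("radial1d", 32, 4),
                 make_grid("axisym2d", c(16, 12), c(2, 3)))) {
    expect_equal(max(abs(laplacian(rep(2.5, g$npts), g))), 0,
                 tolerance = 1e-10)
  }
  # radial: lap(r^2) = 4 exactly at interior points of the flux form
  gr <- make_grid("radial1d", 64, 4)
  lr <- laplacian(gr$coords$r^2, gr)
  expect_equal(lr[-64], rep(4, 63), tolerance = 1e-9)
  # periodic planar: eigenfunction sin(kx), spectral accuracy
  gp <- make_grid("planar1d", 64, 2)
  k <- 2 * pi * 3 / 2
  f <- sin(k * gp$coords$x)
  expect_equal(laplacian(f, gp), -k^2 * f, tolerance = 1e-8)
  # cart3d eigenfunction
  g3 <- make_grid("cart3d", c(12, 10, 8), c(2, 2, 2))
  x <- g3$coords$x
  f3 <- array(rep(sin(2 * pi * x / 2), 10 * 8), g3$dims)
  expect_equal(as.numeric(laplacian(f3, g3)),
               as.numeric(-(pi)^2 * f3), tolerance = 1e-8)
})

test_that("laplacian is self-adjoint and conservative under no-flux", {
  set.seed(42)
  for (g in list(make_grid("planar1d", 40, 4, boundary = "no-flux"),
                 make_grid("radial1d", 40, 4),
                 make_grid("axisym2d", c(20, 16), c(2, 2)))) {
    for (rep in 1:5) {
      f <- rnorm(g$npts); h <- rnorm(g$npts)
      expect_equal(field_inner(f, laplacian(h, g), g),
                   field_inner(laplacian(f, g), h, g), tolerance = 1e-8)
      # divergence theorem: integral of lap(f) vanishes
      expect_lt(abs(integrate_field(laplacian(f, g), g)),
                1e-8 * max(abs(f)) * g$volume)
    }
  }
})

test_that("finite-difference laplacian converges at second order", {
  # lap of cos(pi r^2 / R^2)-type smooth radial field, by refinement
  f_exact <- function(r) exp(-r^2)
  lap_exact <- function(r) (4 * r^2 - 4) * exp(-r^2)
  errs <- vapply(c(50, 100, 200), function(n) {
    g <- make_grid("radial1d", n, 5)
    r <- g$coords$r
    max(abs(laplacian(f_exact(r), g)[-n] - lap_exact(r)[-n]))
  }, numeric(1))
  rate1 <- log2(errs[1] / errs[2])
  rate2 <- log2(errs[2] / errs[3])
  expect_gt(rate1, 1.7); expect_gt(rate2, 1.7)
  expect_lt(rate1, 2.4); expect_lt(rate2, 2.4)
})

test_that("integrate_field applies the geometric measure", {
  gr <- make_grid("radial1d", 100, 3)
  expect_equal(integrate_field(rep(1, 100), gr), pi * 9, tolerance = 1e-12)
  # int 2 pi r * r dr = 2 pi R^3 / 3
  expect_equal(integrate_field(gr$coords$r, gr), 2 * pi * 9, tolerance = 1e-3)
  ga <- make_grid("axisym2d", c(30, 20), c(3, 2))
  expect_equal(integrate_field(rep(1, ga$npts), ga), pi * 9 * 2,
               tolerance = 1e-12)
})
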
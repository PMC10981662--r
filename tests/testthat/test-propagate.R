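test_that("zero fields give the free-chain propagator q = 1 exactly", {
  p <- fast_params()
  for (g in list(make_grid("planar1d", 32, 4),
                 make_grid("radial1d", 32, 4),
                 make_grid("axisym2d", c(12, 10), c(1.5, 2)),
                 make_grid("cart3d", c(6, 6, 6), c(2, 2, 2)))) {
    pr <- propagate(field_state(0, 0, 0, g), g, p)
    expect_lt(max(abs(pr$q - 1)), 1e-10)
    expect_lt(max(abs(pr$qdag - 1)), 1e-10)
    expect_lt(max(abs(pr$qs - 1)), 1e-10)
  }
})

test_that("constant fields give the exponential closed form", {
  p <- fast_params()
  g <- make_grid("planar1d", 32, 4)
  cA <- 1.7; cB <- 0.4
  pr <- propagate(field_state(cA, cB, 0, g), g, p)
  s <- seq(0, 1, by = p$ds)
  wq <- ifelse(s <= p$f, cA * s, cA * p$f + cB * (s - p$f))
  expect_lt(max(abs(sweep(pr$q, 2, exp(-wq), "-"))), 1e-10)
  wdag <- ifelse(s <= 1 - p$f, cB * s, cB * (1 - p$f) + cA * (s - 1 + p$f))
  expect_lt(max(abs(sweep(pr$qdag, 2, exp(-wdag), "-"))), 1e-10)
  ss <- seq(0, p$solvent_ratio, by = p$ds)
  expect_lt(max(abs(sweep(pr$qs, 2, exp(-cB * ss), "-"))), 1e-10)
  # gauge split between w and xi is irrelevant to the propagators
  pr2 <- propagate(field_state(cA - 0.9, cB - 0.9, 0.9, g), g, p)
  expect_identical(pr$q, pr2$q)
})

test_that("contour stepping is second-order accurate in ds", {
  # cosine potential on a periodic grid; reference = Richardson sequence
  g <- make_grid("planar1d", 64, 4)
  w <- 0.8 * cos(2 * pi * g$coords$x / 4)
  fs <- field_state(w, w, 0, g)
  qs <- lapply(c(0.02, 0.01, 0.005), function(ds) {
    p <- scft_params(ds = ds)
    propagate(fs, g, p)$q[, ncol(propagate(fs, g, p)$q)]
  })
  e1 <- max(abs(qs[[1]] - qs[[2]]))
  e2 <- max(abs(qs[[2]] - qs[[3]]))
  rate <- log2(e1 / e2)
  expect_gt(rate, 1.7)
  expect_lt(rate, 2.3)
})

test_that("Crank-Nicolson contour stepping matches spectral stepping", {
  # same physical problem on a no-flux grid wide enough that the
  # mirror-symmetric solution agrees with the periodic spectral one
  p <- fast_params()
  n <- 64
  gp <- make_grid("planar1d", n, 8, boundary = "periodic")
  gn <- make_grid("planar1d", n, 8, boundary = "no-flux")
  w <- 2 * exp(-(gp$coords$x - 4)^2)   # even about the box center
  prp <- propagate(field_state(w, w, 0, gp), gp, p)
  prn <- propagate(field_state(w, w, 0, gn), gn, p)
  expect_lt(max(abs(prp$q - prn$q)), 2e-3)
})

test_that("propagate validates its inputs", {
  p <- fast_params()
  g <- make_grid("planar1d", 32, 4)
  g2 <- make_grid("planar1d", 16, 4)
  fs <- field_state(0, 0, 0, g)
  expect_error(propagate(fs, g2, p), "shape")
  expect_error(field_state(c(Inf, rep(0, 31)), 0, 0, g), "finite")
})
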
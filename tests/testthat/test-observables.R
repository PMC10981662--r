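# synthetic membrane profile with head peaks at chosen positions
synthetic_profile <- function(x, midplane = 0, head_at = 1, core_w = 0.8) {
  pt <- 0.95 * exp(-((x - midplane) / core_w)^4)
  ph <- 0.35 * (exp(-((x - midplane - head_at) / 0.25)^2) +
                exp(-((x - midplane + head_at) / 0.25)^2))
  structure(list(coord = x, phi_tail = pt, phi_head = ph,
                 phi_solvent = pmax(1 - pt - ph, 0), axis = "x"),
            class = "membrane_profile")
}

test_that("bilayer geometry recovers constructed thickness and midplane", {
  x <- seq(-4, 4, by = 0.05)
  prof <- synthetic_profile(x, midplane = 0, head_at = 1)
  geo <- bilayer_geometry(prof)
  expect_equal(geo$thickness, 2, tolerance = 1e-3)
  expect_equal(geo$midplane, 0, tolerance = 1e-6)
  # translation equivariance
  prof2 <- synthetic_profile(x, midplane = 0.6, head_at = 1)
  geo2 <- bilayer_geometry(prof2)
  expect_equal(geo2$midplane - geo$midplane, 0.6, tolerance = 1e-3)
  expect_equal(geo2$thickness, geo$thickness, tolerance = 1e-6)
})

test_that("bilayer geometry rejects empty and multi-core profiles", {
  x <- seq(-4, 4, by = 0.05)
  flat <- structure(list(coord = x, phi_tail = rep(0.01, length(x)) +
                           1e-5 * sin(x),
                         phi_head = rep(0.01, length(x)),
                         phi_solvent = rep(0.98, length(x)), axis = "x"),
                    class = "membrane_profile")
  expect_error(bilayer_geometry(flat), "no bilayer core")
  two <- synthetic_profile(x, midplane = -2, head_at = 0.8)
  two$phi_tail <- two$phi_tail +
    synthetic_profile(x, midplane = 2, head_at = 0.8)$phi_tail
  expect_error(bilayer_geometry(two), "multiple")
})

test_that("fit_kappa recovers exact synthetic rigidity and scaling", {
  sigma <- c(0.05, 0.1, 0.2, 0.4)
  r <- sqrt(20 / (2 * sigma))
  fit <- fit_kappa(r, sigma)
  expect_equal(fit$kappa, 20, tolerance = 1e-8)
  expect_equal(fit$exponent, -0.5, tolerance = 1e-8)
  # kappa x4 -> radii x2 at equal tension
  fit4 <- fit_kappa(2 * r, sigma)
  expect_equal(fit4$kappa, 80, tolerance = 1e-8)
  expect_error(fit_kappa(r[1:3], sigma[c(1, 1, 1)] * c(1, 1.1, 1.2)),
               "degenerate")
})

test_that("radius_from_tension implements the Helfrich tube law", {
  expect_equal(radius_from_tension(2, 1), 1)
  expect_equal(radius_from_tension(8, 1), 2 * radius_from_tension(2, 1))
  # kappa = 20 kT, sigma = 1 mN/m -> about 6.4 nm
  kBT <- 4.11e-21
  r_m <- radius_from_tension(20 * kBT, 1e-3)
  expect_equal(r_m * 1e9, 6.4, tolerance = 0.01)
  expect_error(radius_from_tension(-1, 1), "positive")
  expect_error(radius_from_tension(1, 0), "positive")
})

test_that("unit calibration arithmetic and round trips are exact", {
  um <- unit_map(nm_per_R0 = 2.5)
  expect_equal(um$chain_density, 2.5^3 / 1.26, tolerance = 1e-12)
  # thickness 2.0 R0 with a 5 nm target -> 2.5 nm per R0
  expect_equal(5 / 2.0, um$nm_per_R0)
  x <- 1.234
  expect_equal(sigma_dyn_cm_to_kBT(sigma_kBT_to_dyn_cm(x, um), um), x,
               tolerance = 1e-12)
  expect_equal(sigma_dyn_cm_to_model(sigma_model_to_dyn_cm(x, um), um), x,
               tolerance = 1e-12)
  # 1 Dyn/cm corresponds to 0.2433... nm_per_R0^2 in kT/R0^2
  s_model <- sigma_dyn_cm_to_kBT(1, um)
  expect_equal(s_model, um$nm_per_R0^2 / 4.11, tolerance = 1e-12)
  expect_equal(s_model / um$nm_per_R0^2, 0.2433, tolerance = 1e-3)
})

test_that("physical-unit outputs are pure rescalings of model results", {
  # recomputing with a different thickness target rescales nm values and
  # leaves R0-unit results untouched
  um5 <- unit_map(nm_per_R0 = 2.5)
  um6 <- unit_map(nm_per_R0 = 3.0)
  r_R0 <- 1.7
  expect_equal((r_R0 * um6$nm_per_R0) / (r_R0 * um5$nm_per_R0), 3.0 / 2.5)
})

test_that("tension requires a converged planar state", {
  p <- fast_params(mu = 11.5)
  g <- make_grid("radial1d", 24, 3)
  fake <- structure(list(grid = g), class = "scft_state")
  expect_error(tension(fake), "planar1d")
})

test_that("tube_radius orders nested membranes and checks the count", {
  # synthetic double-membrane radial profile
  r <- seq(0.025, 8, by = 0.05)
  mk <- function(mid) synthetic_profile(r, midplane = mid, head_at = 0.6)
  pin <- mk(1.5); pout <- mk(4)
  dens <- density_state(pin$phi_tail + pout$phi_tail,
                        pin$phi_head + pout$phi_head,
                        pmax(1 - pin$phi_tail - pout$phi_tail -
                             pin$phi_head - pout$phi_head, 0),
                        make_grid("radial1d", length(r), 8))
  st <- structure(list(grid = make_grid("radial1d", length(r), 8),
                       dens = dens), class = "scft_state")
  tr <- tube_radius(st, n_membranes = 2)
  expect_equal(tr$radii, c(1.5, 4), tolerance = 0.01)
  expect_gt(tr$radii[2], tr$radii[1] + tr$thickness[1])
  expect_error(tube_radius(st, n_membranes = 1), "expected 1")
})
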
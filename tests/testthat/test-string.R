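test_that("density distance is a metric on random density triples", {
  set.seed(11)
  g <- make_grid("planar1d", 32, 4)
  rand_dens <- function() {
    a <- matrix(runif(32 * 3), 32, 3)
    a <- a / rowSums(a)
    density_state(a[, 1], a[, 2], a[, 3], g)
  }
  a <- rand_dens()
  expect_equal(density_distance(a, a, g), 0)
  for (i in 1:100) {
    x <- rand_dens(); y <- rand_dens(); z <- rand_dens()
    dxy <- density_distance(x, y, g)
    expect_equal(dxy, density_distance(y, x, g), tolerance = 1e-12)
    expect_lte(dxy, density_distance(x, z, g) +
                    density_distance(z, y, g) + 1e-12)
    expect_gte(dxy, 0)
  }
})

test_that("reparametrization equalizes arc length and preserves endpoints", {
  set.seed(5)
  # random 10-node path in a 40-dof space
  nodes <- list(rnorm(40))
  for (m in 2:10) nodes[[m]] <- nodes[[m - 1]] + rnorm(40, sd = runif(1, 0.2, 2))
  path <- string_path(nodes)
  rp <- reparametrize(path)
  seg <- memfis:::path_segments(rp)
  expect_lt(stats::sd(seg) / mean(seg), 1e-3)
  expect_identical(rp$nodes[[1]], nodes[[1]])
  expect_identical(rp$nodes[[10]], nodes[[10]])
  # an already-equal path is returned unchanged to round-off
  rp2 <- reparametrize(rp)
  expect_equal(unlist(rp2$nodes), unlist(rp$nodes), tolerance = 1e-7)
  # on a smooth, well-resolved path the total arc length is preserved
  ts <- seq(0, 1, length.out = 25)
  smooth <- lapply(ts, function(t) c(cos(pi * t), sin(pi * t), t^2))
  sp <- string_path(smooth)
  sp2 <- reparametrize(sp)
  expect_equal(sum(memfis:::path_segments(sp2)),
               sum(memfis:::path_segments(sp)), tolerance = 0.01)
})

test_that("two-node bridge densified to 3 nodes averages the endpoints", {
  a <- rep(0, 8); b <- rep(2, 8)
  path <- string_path(list(a, b))
  rp <- reparametrize(path, n_nodes = 3)
  expect_equal(rp$nodes[[2]], (a + b) / 2, tolerance = 1e-12)
})

test_that("degenerate zero-length paths are rejected", {
  a <- rep(1, 5)
  expect_error(reparametrize(string_path(list(a, a, a))), "degenerate")
})

test_that("barrier extraction matches hand-computed profiles", {
  pf <- energy_profile(c(0, .25, .5, .75, 1), c(0, 1, 0.5, 2, 0))
  br <- extract_barriers(pf)
  expect_equal(br$alpha_peak, c(0.25, 0.75))
  expect_equal(br$dF_forward, c(1.0, 1.5))
  expect_equal(attr(br, "rate_limiting"), 1.5)
  # shift invariance
  br2 <- extract_barriers(energy_profile(c(0, .25, .5, .75, 1),
                                         c(0, 1, 0.5, 2, 0) + 7))
  expect_equal(br2$dF_forward, br$dF_forward)
  # monotone profile -> no barriers
  br3 <- extract_barriers(energy_profile(seq(0, 1, 0.25), 5:1))
  expect_equal(nrow(br3), 0L)
  expect_error(extract_barriers(energy_profile(c(0, 1), c(0, 0))),
               "at least 5")
})

test_that("string method matches brute-force search on the two-well fixture", {
  barrier_true <- twowell_saddle_bruteforce() - twowell_minimum()$value
  errs <- vapply(c(10, 20, 40), function(M)
    abs(twowell_string_barrier(M)$barrier - barrier_true) / barrier_true,
    numeric(1))
  expect_lt(errs[2], 0.01)          # 1% at the default node count
  expect_true(all(diff(errs) < 0))  # error decreases with node count
})

test_that("a string on a constant-energy landscape is stationary", {
  set.seed(3)
  nodes <- lapply(seq(0, 1, length.out = 7), function(f)
    c(f, 0.5 * sin(pi * f)))
  path <- string_path(nodes)
  relax_fun <- function(v, steps) list(node = v, metric = v, energy = 4.2)
  res <- string_relax(path, relax_fun, n_outer = 10, inner_steps = 3,
                      tol = 1e-8)
  expect_true(res$converged)
  expect_equal(res$profile$F, rep(4.2, 7))
  # nodes stay on the (reparametrized) initial path: any path is stationary
  expect_equal(unlist(res$path$nodes), unlist(reparametrize(path)$nodes),
               tolerance = 1e-6)
})

test_that("SCFT string endpoints reproduce the converged free energies", {
  p <- fast_params(mu = 11.5)
  g <- make_grid("planar1d", 32, 4)
  a <- scft_converge(seed_topology("planar_bilayer", g, p, center = 1.8),
                     p, g, beta = 0.8, max_iter = 4000)
  b <- scft_converge(seed_topology("planar_bilayer", g, p, center = 2.2),
                     p, g, beta = 0.8, max_iter = 4000)
  res <- relax_string(list(a, b), p, g, M = 5, n_outer = 3,
                      inner_steps = 1, n_inverse = 80)
  expect_equal(res$profile$F[1], a$excess_free_energy, tolerance = 1e-4)
  expect_equal(res$profile$F[5], b$excess_free_energy, tolerance = 1e-4)
  expect_true(all(is.finite(res$profile$F)))
  # interior nodes pass through higher free energy than the translated
  # bilayer endpoints (superposed configurations cost energy)
  expect_true(all(res$profile$F[2:4] > a$excess_free_energy - 1e-6))
  # identical endpoints give a flat profile
  res2 <- relax_string(list(a, a), p, g, M = 5, n_outer = 2,
                       inner_steps = 1, n_inverse = 40)
  expect_equal(res2$profile$F, rep(a$excess_free_energy, 5),
               tolerance = 1e-6)
})
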
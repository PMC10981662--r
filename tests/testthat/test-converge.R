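test_that("an already-converged state is a fixed point at iteration 0", {
  p <- fast_params(mu = 2)
  g <- make_grid("planar1d", 24, 3)
  hom <- solve_homogeneous(p, "solvent")
  st <- scft_converge(field_state(hom$W_A, hom$W_B, 0, g), p, g,
                      tol = 1e-8, max_iter = 100)
  expect_true(st$converged)
  expect_identical(st$iterations, 0L)
  expect_equal(st$residual_history$residual[1],
               min(st$residual_history$residual))
})

test_that("planar tanh seed converges to a bilayer with a tail-rich core", {
  p <- fast_params(mu = 11.5)
  g <- make_grid("planar1d", 80, 8)
  st <- scft_converge(seed_topology("planar_bilayer", g, p), p, g,
                      beta = 0.8, max_iter = 4000)
  expect_true(st$converged)
  prof <- membrane_profile(st)
  expect_gt(max(prof$phi_tail), 0.9)     # tail-rich hydrophobic core
  # head-rich layers flank the core: head maxima exceed head fraction in bulk
  expect_gt(max(prof$phi_head), 5 * prof$phi_head[1])
  # incompressibility enforced exactly at convergence
  expect_lt(st$incompressibility, 1e-5)
})

test_that("residual history is monotone-ish and recorded per iteration", {
  p <- fast_params(mu = 11.5)
  g <- make_grid("planar1d", 48, 6)
  st <- scft_converge(seed_topology("planar_bilayer", g, p), p, g,
                      beta = 0.8, max_iter = 4000)
  h <- st$residual_history
  expect_true(all(diff(h$iter) > 0))
  expect_lt(utils::tail(h$residual, 1), 1e-6)
  expect_true(all(is.finite(h$free_energy)))
})

test_that("iteration-budget exhaustion raises a classed error with residual", {
  p <- fast_params(mu = 11.5)
  g <- make_grid("planar1d", 48, 6)
  err <- tryCatch(
    scft_converge(seed_topology("planar_bilayer", g, p), p, g,
                  max_iter = 3, on_max_iter = "error"),
    scft_max_iter = function(e) e)
  expect_s3_class(err, "scft_max_iter")
  expect_true(is.finite(err$residual))
  expect_warning(
    scft_converge(seed_topology("planar_bilayer", g, p), p, g,
                  max_iter = 3, on_max_iter = "warn"),
    "did not converge")
})

test_that("model parameter invariants are enforced", {
  expect_error(scft_params(f = 1.2), "f")
  expect_error(scft_params(chiN = -1), "chiN")
  expect_error(scft_params(f = 0.856, ds = 0.01), "integer")
  expect_error(scft_params(ds = 0.013), "integer")
})
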
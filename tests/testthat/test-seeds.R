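test_that("dm_tube seed places nested cores at thickness + gap separation", {
  p <- fast_params()
  g <- make_grid("radial1d", 120, 12)
  fs <- seed_topology("dm_tube", g, p, r_in = 3, gap = 1, thickness = 1.8)
  phi <- attr(fs, "phi_tail")
  cores <- memfis:::tail_cores(phi)
  expect_length(cores, 2)
  centers <- vapply(cores, function(run)
    sum(g$coords$r[run] * phi[run]) / sum(phi[run]), numeric(1))
  expect_equal(diff(sort(centers)), 1.8 + 1, tolerance = 0.05)
})

test_that("seed fields are the chiN-scaled tail indicator", {
  p <- fast_params()
  g <- make_grid("planar1d", 48, 6)
  fs <- seed_topology("planar_bilayer", g, p)
  phi <- attr(fs, "phi_tail")
  expect_equal(fs$w_B, p$chiN * phi)
  expect_equal(fs$w_A, p$chiN * (1 - phi))
  expect_true(all(fs$xi == 0))
})

test_that("geometric infeasibility is rejected", {
  p <- fast_params()
  g <- make_grid("radial1d", 60, 6)
  ga <- make_grid("axisym2d", c(20, 16), c(2.5, 2))
  expect_error(seed_topology("dm_tube", g, p, r_in = 2, gap = -0.5),
               "non-negative")
  expect_error(seed_topology("dm_tube", g, p, r_in = 4, gap = 2), "fit")
  expect_error(seed_topology("sm_tube", g, p, r0 = 0.3), "exceed")
  expect_error(seed_topology("stalk", ga, p, separation = 0.5), "overlap")
  expect_error(seed_topology("pore", ga, p, pore_radius = -1), "positive")
  expect_error(seed_topology("stalk", g, p, separation = 3), "axisym2d")
})

test_that("axisymmetric seeds build the advertised shapes", {
  p <- fast_params()
  g <- make_grid("axisym2d", c(30, 40), c(3, 4))
  nr <- 30
  # pore: tail absent on the axis, present off-axis at the bilayer plane
  fs <- seed_topology("pore", g, p, pore_radius = 1, center_z = 2)
  phi <- matrix(attr(fs, "phi_tail"), 30, 40)
  iz <- 20   # z = 1.95, at the bilayer
  expect_lt(phi[1, iz], 0.1)
  expect_gt(phi[25, iz], 0.9)
  # wlm bridge: tail on the axis at mid-z, absent beyond the capsule
  fs2 <- seed_topology("wlm_bridge", g, p, length = 2, center_z = 2)
  phi2 <- matrix(attr(fs2, "phi_tail"), 30, 40)
  expect_gt(phi2[1, 20], 0.9)
  expect_lt(phi2[1, 38], 0.1)
  # capped tube: annular core below the cap, closed above
  fs3 <- seed_topology("capped_tube", g, p, r0 = 1.5, cap_z = 2)
  phi3 <- matrix(attr(fs3, "phi_tail"), 30, 40)
  expect_gt(phi3[15, 5], 0.9)    # r = 1.45 inside the wall
  expect_lt(phi3[1, 5], 0.1)     # lumen open below the cap
  expect_lt(phi3[15, 40], 0.1)   # beyond the cap
})
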
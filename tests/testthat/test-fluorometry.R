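test_that("radius from fluorescence is exact algebra", {
  expect_equal(radius_from_fluorescence(2 * pi * 10, 10), 1)
  expect_equal(radius_from_fluorescence(0, 3), 0)
  expect_equal(radius_from_fluorescence(628.3185, 10), 10, tolerance = 1e-4)
  # linear in F_l, inverse in D
  expect_equal(radius_from_fluorescence(4, 2),
               2 * radius_from_fluorescence(2, 2))
  expect_equal(radius_from_fluorescence(4, 4),
               radius_from_fluorescence(4, 2) / 2)
  expect_error(radius_from_fluorescence(1, 0), "positive")
  expect_error(radius_from_fluorescence(-1, 1), "non-negative")
})

test_that("inner-radius estimate follows the midplane convention", {
  expect_equal(inner_radius(13.7, gap_nm = 2), 6.7)
  expect_equal(inner_radius(13.7, gap_nm = 5), 3.7)
  expect_equal(inner_radius(10, gap_nm = 0, thickness_nm = 0), 10)
  # round trip: outer reconstruction is exact
  r_in <- inner_radius(13.7, 2)
  expect_equal(r_in + 5 + 2, 13.7)
  expect_error(inner_radius(6, gap_nm = 2), "infeasible")
})

test_that("noiseless line scans round-trip the radius through F_l/2piD", {
  sc <- synth_line_scan(r = 0.8, D = 25, n = 3, noise_sd = 0, seed = 2)
  r_rec <- radius_from_fluorescence(sc$F_l, sc$D)
  expect_equal(r_rec, rep(0.8, 3), tolerance = 1e-6)
  # DM doubles the signal exactly at zero noise
  sc2 <- synth_line_scan(r = 0.8, D = 25, lamellarity = c("SM", "DM"),
                         n = 2, noise_sd = 0, seed = 2)
  expect_equal(sc2$F_l[2] / sc2$F_l[1], 2, tolerance = 1e-10)
})

test_that("noisy radius recovery is unbiased at the 1% level", {
  sc <- synth_line_scan(r = 1.2, D = 40, n = 500, noise_sd = 0.05,
                        seed = 123)
  r_rec <- radius_from_fluorescence(sc$F_l, sc$D)
  expect_equal(mean(r_rec), 1.2, tolerance = 0.01)
  expect_equal(stats::sd(r_rec) / mean(r_rec), 0.05, tolerance = 0.25)
})

test_that("lamellarity classification reaches 98% on the synthetic benchmark", {
  m <- 50
  sc <- synth_line_scan(r = m / (2 * pi * 10), D = 10, n = 200,
                        lamellarity = rep(c("SM", "DM"), 100),
                        noise_sd = 0.10, seed = 42)
  cl <- classify_lamellarity(sc$F_l)
  acc <- mean(cl$labels == sc$lamellarity)
  expect_gte(acc, 0.98)
  expect_false(cl$warning)
  expect_equal(unname(cl$centers["DM"] / cl$centers["SM"]), 2,
               tolerance = 0.15)
})

test_that("unimodal samples fall back to all-SM with a warning flag", {
  set.seed(9)
  cl <- classify_lamellarity(rnorm(100, 50, 2))
  expect_true(all(cl$labels == "SM"))
  expect_true(cl$warning)
  expect_error(classify_lamellarity(numeric(0)), "empty")
  expect_error(classify_lamellarity(rep(1, 5)), "at least 10")
})
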
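test_that("config schema violations are reported with the offending field", {
  expect_error(validate_config(list(run = "fly")), "'run'")
  expect_error(validate_config(list(run = "converge", bogus = 1)),
               "bogus")
  expect_error(validate_config(list(run = "converge",
                                    params = list(f = 1.2),
                                    grid = list(kind = "planar1d", n = 16,
                                                extent = 2))),
               "f")
  expect_error(validate_config(list(run = "converge",
                                    params = list(chiN = 30))),
               "grid")
  cfg <- validate_config(list(run = "converge",
                              grid = list(kind = "planar1d", n = 16,
                                          extent = 2)))
  expect_s3_class(cfg$params, "scft_params")
  expect_s3_class(cfg$grid, "scft_grid")
})

test_that("converge run writes checkpoint, history and log; reruns are byte-identical", {
  cfg <- list(run = "converge",
              params = list(mu = 11.5, ds = 0.02),
              grid = list(kind = "planar1d", n = 48, extent = 6),
              converge = list(max_iter = 4000),
              seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_config(cfg, d1)
  r2 <- run_config(cfg, d2)
  expect_true(file.exists(file.path(d1, "state.json")))
  expect_true(file.exists(file.path(d1, "residual_history.csv")))
  expect_true(file.exists(file.path(d1, "log.txt")))
  expect_lt(r1$summary$final_residual, 1e-6)
  expect_identical(readLines(file.path(d1, "residual_history.csv")),
                   readLines(file.path(d2, "residual_history.csv")))
  # every CSV embeds the config hash
  first <- readLines(file.path(d1, "residual_history.csv"), n = 1)
  expect_match(first, r1$summary$config_hash)
})

test_that("checkpoints round-trip states through JSON", {
  p <- fast_params(mu = 11.5)
  g <- make_grid("planar1d", 32, 4)
  st <- scft_converge(seed_topology("planar_bilayer", g, p), p, g,
                      beta = 0.8, max_iter = 4000)
  f <- tempfile(fileext = ".json")
  write_checkpoint(st, f)
  st2 <- read_checkpoint(f)
  expect_equal(st2$fields$w_A, st$fields$w_A, tolerance = 1e-12)
  expect_equal(st2$dens$phi_tail, st$dens$phi_tail, tolerance = 1e-12)
  expect_equal(st2$free_energy, st$free_energy, tolerance = 1e-12)
  expect_equal(st2$grid$extent, st$grid$extent)
  expect_equal(st2$params$mu, st$params$mu)
})

test_that("fluor run classifies the synthetic sample it generates", {
  cfg <- list(run = "fluor",
              fluor = list(r = 1, D = 10, n = 60,
                           lamellarity = rep(c("SM", "DM"), 30),
                           noise_sd = 0.08),
              seed = 3)
  out <- run_config(cfg, tempfile())
  expect_gte(out$summary$accuracy, 0.95)
})
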
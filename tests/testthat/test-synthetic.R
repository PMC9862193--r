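# synthetic_data: determinism, the zero-noise identity, the noise-model
# oracle, and bundle schema round-trips.

fx_truth_traj <- function() ff_cached("truth_traj2", {
  ss <- fx_steady()
  run_cycles(ss, fx_calib(), fx_proto(), n_cycles = 2, out_dt = 2,
             keep = "last", rtol = 1e-7, atol = 1e-9)
})

test_that("zero-noise bundle equals the noiseless model output at the grid", {
  traj <- fx_truth_traj()
  sp <- synthetic_spec(cv_conc = 0, cv_flux = 0, seed = 3, n_cycles = 2,
                       conc_species = c("G6P", "GLCec"),
                       flux_reactions = "HXK", flux_nodes = 25)
  b <- generate_bundle(sp, truth_trajectory = traj)
  for (spp in c("G6P", "GLCec")) {
    d <- b$concentrations[b$concentrations$species == spp, ]
    truth <- approx(traj$time, traj$states[, spp], xout = d$time_s)$y
    expect_equal(d$value, truth, tolerance = 1e-12)
  }
  # fluxes are reported as piecewise-linear resamplings over 25-s nodes
  d <- b$fluxes
  nodes <- seq(0, 400, by = 25)
  at_nodes <- approx(traj$time, traj$fluxes[, "HXK"], xout = nodes)$y
  expect_equal(d$value, approx(nodes, at_nodes, xout = d$time_s)$y,
               tolerance = 1e-12)
})

test_that("bundles are bitwise reproducible per seed and differ across seeds", {
  traj <- fx_truth_traj()
  sp <- synthetic_spec(seed = 11, n_cycles = 2,
                       conc_species = c("G6P", "T6P"), flux_reactions = "HXT")
  b1 <- generate_bundle(sp, truth_trajectory = traj)
  b2 <- generate_bundle(sp, truth_trajectory = traj)
  expect_identical(b1$concentrations$value, b2$concentrations$value)
  sp$seed <- 12
  b3 <- generate_bundle(sp, truth_trajectory = traj)
  expect_false(identical(b1$concentrations$value, b3$concentrations$value))
})

test_that("empirical noise CV matches the configured CV (replicate oracle)", {
  traj <- fx_truth_traj()
  sp <- synthetic_spec(seed = 1, n_cycles = 2, cv_conc = 0.05,
                       conc_species = "G6P", flux_reactions = "HXT",
                       grid = c(20, 100), cv_flux = 0.10)
  draws_c <- numeric(1000); draws_f <- numeric(1000)
  for (k in 1:1000) {
    sp$seed <- k
    b <- generate_bundle(sp, truth_trajectory = traj)
    draws_c[k] <- b$concentrations$value[1]
    draws_f[k] <- b$fluxes$value[1]
  }
  expect_equal(sd(draws_c) / mean(draws_c), 0.05, tolerance = 0.05)
  expect_equal(sd(draws_f) / mean(draws_f), 0.10, tolerance = 0.05)
  # sd column is CV x value
  expect_equal(b$concentrations$sd, 0.05 * b$concentrations$value)
})

test_that("noiseless bundle round-trips through a zero-error fit", {
  traj <- fx_truth_traj()
  sp <- synthetic_spec(cv_conc = 0, cv_flux = 0, seed = 2, n_cycles = 2,
                       conc_species = c("G6P", "GLCec", "T6P"),
                       flux_reactions = c("HXT", "HXK"),
                       grid = seq(20, 380, by = 60), flux_nodes = 20)
  b <- generate_bundle(sp, truth_trajectory = traj)
  cfg <- estimation_config(character(0), base = sp$truth, n_cycles_fit = 2,
                           rtol = 1e-7, atol = 1e-9)
  fit <- fit_subset(cfg, b)
  # free set empty, truth parameters: data error only reflects grid
  # interpolation and flux-node resampling differences
  expect_lt(fit$data_error, 0.05)
})

test_that("bundle schema validates for arbitrary seeds", {
  traj <- fx_truth_traj()
  for (sd in c(101, 202)) {
    sp <- synthetic_spec(seed = sd, n_cycles = 2,
                         conc_species = c("G6P", "FBP"), flux_reactions = "PYK")
    b <- generate_bundle(sp, truth_trajectory = traj)
    expect_s3_class(b, "observation_bundle")
    expect_true(all(b$concentrations$sd > 0))
    expect_true(all(b$fluxes$time_s >= 0 & b$fluxes$time_s <= 400))
  }
})
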
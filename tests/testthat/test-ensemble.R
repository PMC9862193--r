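# ensemble_analysis: sampling semantics, degenerate cases, and the
# feasibility-scan plumbing (the full negative result runs in the
# acceptance suite).

test_that("ensemble spec validates and r = 0 degenerates to no dispersion", {
  expect_error(ensemble_spec(n = 0))
  expect_error(ensemble_spec(range = 0))
  spec <- ensemble_spec(n = 4, range = 1e-12, seed = 2)
  ens <- perturb_ensemble(fx_calib(), spec, n_cycles = 1, out_dt = 50)
  expect_equal(ens$n_ok, 4)
  expect_lt(max(ens$dispersion$median_rel_sd), 1e-6)
})

test_that("sample mean of perturbation factors approaches 1 (law of large numbers)", {
  spec <- ensemble_spec(n = 1000, range = 0.10, seed = 8)
  keys <- feastfamine:::.perturbable("all")
  set.seed(spec$seed)
  factors <- matrix(runif(spec$n * length(keys), 0.9, 1.1), spec$n)
  expect_lt(max(abs(colMeans(factors) - 1)), 0.01)
})

test_that("HXT-only scope perturbs only transporter constants", {
  keys <- feastfamine:::.perturbable("HXT")
  expect_setequal(keys, c("HXT.Vmax", "HXT.Km", "HXT.Ki"))
})

test_that("feasibility scan honours a degenerate threshold", {
  # with eps = Inf the constraint at 400 s is vacuous, so any passive sample
  # that reaches the 20-s target makes the scan 'feasible'
  tr <- ff_cached("glc_trace", reference_glcec_trace(fx_calib(), fx_proto()))
  scan <- ff_cached("scan_small",
    hxt_feasibility_scan(fx_calib(), ensemble_spec(n = 12, decades = 3, seed = 5),
                         fx_proto(), glcec_trace = tr))
  relaxed <- with(scan$samples, ok & uptake_20s >= scan$target)
  if (any(relaxed, na.rm = TRUE)) {
    scan_inf <- scan
    expect_true(any(with(scan$samples,
                         ok & uptake_20s >= scan$target & uptake_400s <= Inf),
                    na.rm = TRUE))
  }
  # a sample evaluated at the estimated constants with sensing off lies on
  # the proportional trade-off frontier: substantial uptake at both times
  p_off <- parameter_set(c("HXT.sensing" = 0), base = fx_calib())
  tabs <- glycogen_tables()
  env <- phase_env(fx_proto(), "batch", tables = tabs, clamp = tr)
  times <- seq(0, 1200, by = 2)
  r <- integrate_model(as.numeric(shipped_steady_state()), times, p_off, env,
                       rtol = 1e-6, atol = 1e-8)
  expect_true(r$ok)
  v20 <- feastfamine:::cpp_fluxes(r$y[which.min(abs(times - 820)), ], 820,
                                  as.numeric(p_off), env)[["HXT"]]
  v400 <- feastfamine:::cpp_fluxes(r$y[nrow(r$y), ], 1200,
                                   as.numeric(p_off), env)[["HXT"]]
  expect_gt(v400, 0.02)     # passive kinetics cannot shut down at famine end
  expect_gt(v20, v400)
})
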
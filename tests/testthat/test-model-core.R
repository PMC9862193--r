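# model_core: registries, rate laws against formula oracles, right-hand-side
# assembly against the compiled fast path, structural invariants.

test_that("R registries agree with the compiled registries", {
  info <- feastfamine:::cpp_model_info()
  expect_identical(model_species(), as.character(info$species))
  expect_identical(model_reactions(), as.character(info$reactions))
  expect_identical(model_parameters(), as.character(info$parameters))
  S <- stoichiometry_matrix()
  expect_identical(rownames(S), model_species())
  expect_identical(colnames(S), model_reactions())
})

test_that("HXT kinetics: gradient zero-point, threshold clamp, formula oracle", {
  p <- fx_calib()
  # zero trans-membrane gradient, sensing off, Keq = 1 -> zero rate
  expect_equal(rate_hxt(1.3, 1.3, p, sensing = FALSE), 0)
  # antisymmetry under substrate swap (sensing off)
  for (pair in list(c(0.2, 1.9), c(2.5, 0.1), c(0.7, 0.7))) {
    expect_equal(rate_hxt(pair[1], pair[2], p, sensing = FALSE),
                 -rate_hxt(pair[2], pair[1], p, sensing = FALSE), tolerance = 1e-12)
  }
  # uptake shut off at the sensing threshold
  expect_equal(rate_hxt(p[["HXT.GLCec_min"]], 0, p, sensing = TRUE), 0)
  expect_equal(rate_hxt(p[["HXT.GLCec_min"]] * 0.5, 0, p, sensing = TRUE), 0)
  # Table-backed constants, hand-evaluated formula at a chosen state
  Vm <- 1.70; Km <- 0.90
  p2 <- parameter_set(c("HXT.Vmax" = Vm, "HXT.Km" = Km, "HXT.Ki" = 0.5,
                        "HXT.GLCec_min" = 0.4), base = p)
  ge <- 2.3; gi <- 0.35
  x <- ge - 0.4
  hand <- (Vm / Km) * (x - gi) / (1 + x / Km + gi / Km + x * gi / (0.5 * Km^2))
  expect_equal(rate_hxt(ge, gi, p2, sensing = TRUE), hand, tolerance = 1e-14)
  expect_error(rate_hxt(-1, 0, p), "negative")
})

test_that("reversible uni-uni MM: equilibrium, inhibition limit, oracle", {
  # equilibrium: s * Keq = prod -> zero net rate
  expect_equal(rate_mm_rev(0.4, 0.4 * 2.5, 1, 0.3, 0.7, 2.5), 0)
  # full inhibition limit
  expect_lt(rate_mm_rev(1, 0.1, 1, 0.3, 0.7, 2.5, inhibitor = 1e9, Ki = 1), 1e-9)
  # random admissible states against the hand-written rational expression
  set.seed(4)
  for (i in 1:25) {
    s <- runif(1, 0, 5); pr <- runif(1, 0, 5)
    Vm <- runif(1, 0.1, 3); Ks <- runif(1, 0.05, 2); Kp <- runif(1, 0.05, 2)
    Keq <- runif(1, 0.2, 5)
    hand <- (Vm / Ks) * (s - pr / Keq) / (1 + s / Ks + pr / Kp)
    expect_equal(rate_mm_rev(s, pr, Vm, Ks, Kp, Keq), hand, tolerance = 1e-13)
  }
})

test_that("irreversible MM: zero substrate, half-saturation, saturation limit", {
  expect_equal(rate_mm_irrev(0, 2, 0.5), 0)
  expect_equal(rate_mm_irrev(0.5, 2, 0.5), 1)       # s = Km -> Vmax/2
  expect_equal(rate_mm_irrev(1e9, 2, 0.5), 2, tolerance = 1e-8)
  expect_gte(rate_mm_irrev(0.3, 2, 0.5, inhibitor = 10, Ki = 1), 0)
})

test_that("ordered bi-bi UGP: zero substrates, sign reversal, formula oracle", {
  p <- fx_calib()
  expect_equal(rate_ugp(0, 0, 0, 0, p), 0)
  fwd <- rate_ugp(1, 2, 0.01, 0.01, p)
  expect_gt(fwd, 0)
  # product-dominated regime flips the net rate sign
  rev <- rate_ugp(1e-4, 1e-4, 20, 20, p)
  expect_lt(rev, 0)
  A <- 0.3; B <- 1.8; P <- 0.5; Q <- 0.9
  Ka <- p[["UGP.Km_G1P"]]; Kb <- p[["UGP.Km_ATP"]]; Kia <- p[["UGP.Kia_G1P"]]
  Kp <- p[["UGP.Km_UDPG"]]; Kq <- p[["UGP.Km_ADP"]]
  hand <- p[["UGP.Vmax"]] * (A * B - P * Q / p[["UGP.Keq"]]) /
    (Kia * Kb * (1 + P / Kp + Q / Kq + P * Q / (Kp * Kq)) +
       Kb * A + Ka * B + A * B)
  expect_equal(rate_ugp(A, B, P, Q, p), hand, tolerance = 1e-14)
})

test_that("glycogen flux: saturation factors and interpolation oracle", {
  tab <- data.frame(time_s = c(0, 50, 100, 400),
                    flux_mM_per_s = c(0.01, 0.05, 0.02, 0.01))
  expect_equal(rate_glycogen(75, 0, tab, Ksat = 0.1), 0)
  # deep saturation approaches the interpolated base rate
  expect_equal(rate_glycogen(50, 1e9, tab, Ksat = 0.1), 0.05, tolerance = 1e-7)
  # linear interpolant at t = 75 computed by hand: midpoint of 0.05 and 0.02
  hand <- 0.035 * 0.4 / (0.4 + 0.1)
  expect_equal(rate_glycogen(75, 0.4, tab, Ksat = 0.1), hand, tolerance = 1e-12)
  # periodic extension across cycles
  expect_equal(rate_glycogen(475, 0.4, tab, Ksat = 0.1),
               rate_glycogen(75, 0.4, tab, Ksat = 0.1))
  expect_error(rate_glycogen(450, 0.4, tab, Ksat = 0.1, periodic = FALSE),
               "outside")
})

test_that("allosteric and Hill laws: limits, MM degeneracy, FBP monotonicity", {
  p <- fx_calib()
  expect_equal(rate_pfk(0, 2, 0.3, 0.1, p), 0)
  expect_equal(rate_pyk(0, 1, 0.2, p), 0)
  expect_equal(rate_pdc(0, p), 0)
  # Hill n = 1 reduces exactly to Michaelis-Menten
  p1 <- parameter_set(c("PDC.n" = 1), base = p)
  s <- c(0.2, 1, 4)
  expect_equal(rate_pdc(s, p1),
               p[["PDC.Vmax"]] * s / (p[["PDC.K05"]] + s), tolerance = 1e-13)
  # PYK strictly increases with FBP at fixed substrates (finite-difference grid)
  fbp <- seq(0, 3, by = 0.25)
  for (pep in c(0.2, 0.8, 2)) {
    v <- rate_pyk(pep, 1.0, fbp, p)
    expect_true(all(diff(v) > 0))
  }
})

test_that("irreversible reactions never return negative rates", {
  p <- fx_calib()
  rev <- reaction_reversible()
  env <- fx_env()
  worst <- 0
  for (i in 1:200) {                       # 200 states x 34 reactions
    y <- fx_random_state(i)
    v <- model_fluxes(y, runif(1, 0, 400), p, env)
    worst <- min(worst, min(v[!rev]))
  }
  expect_gte(worst, 0)
})

test_that("moiety vectors lie in the left null space of the stoichiometry", {
  S <- stoichiometry_matrix()
  aden <- as.numeric(rownames(S) %in% c("ATP", "ADP", "AMP"))
  nad <- as.numeric(rownames(S) %in% c("NAD", "NADH"))
  expect_equal(max(abs(aden %*% S)), 0)
  expect_equal(max(abs(nad %*% S)), 0)
})

test_that("R right-hand side equals the compiled fast path (oracle equivalence)", {
  p <- fx_calib()
  for (phase in c("chemostat", "feed", "outflow", "batch")) {
    env <- fx_env(phase)
    for (i in 1:5) {
      y <- fx_random_state(100 + i)
      t <- runif(1, 0, 400)
      vR <- model_fluxes(y, t, p, env)
      vC <- feastfamine:::cpp_fluxes(as.numeric(y), t, as.numeric(p), env)
      expect_equal(max(abs(vR - vC)), 0, tolerance = 1e-12)
      dR <- ode_rhs_total(y, t, p, env)
      dC <- feastfamine:::cpp_rhs(as.numeric(y), t, as.numeric(p), env)
      expect_equal(max(abs(dR - dC)), 0, tolerance = 1e-12)
    }
  }
})

test_that("degenerate inputs: all-zero capacity and closed system freeze the state", {
  p <- fx_calib()
  vkeys <- grep("\\.(Vmax|k)$", model_parameters(), value = TRUE)
  p0 <- parameter_set(setNames(rep(1e-300, length(vkeys)), vkeys), base = p)
  p0[["PIBUF.k"]] <- 1e-300
  env <- fx_env("batch")
  y <- as.numeric(shipped_steady_state())
  # glycogen forcing tables are protocol inputs, not Vmax-scaled; zero them too
  env$gly_syn_v <- env$gly_syn_v * 0
  env$gly_deg_v <- env$gly_deg_v * 0
  dy <- ode_rhs_total(shipped_steady_state(), 0, p0, env)
  expect_lt(max(abs(dy)), 1e-250)
})

test_that("chemostat steady state of the shipped calibrated set is exact", {
  ss <- fx_steady()
  expect_lt(attr(ss, "residual"), 1e-6)
  expect_true(all(as.numeric(ss) > 0))
})

test_that("adenylate and NAD(H) sums are conserved along the whole regime", {
  traj <- fx_traj20()
  aden <- rowSums(traj$states[, c("ATP", "ADP", "AMP")])
  nad <- rowSums(traj$states[, c("NAD", "NADH")])
  expect_lt(max(abs(aden - aden[1])) / aden[1], 1e-6)
  expect_lt(max(abs(nad - nad[1])) / nad[1], 1e-6)
})
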
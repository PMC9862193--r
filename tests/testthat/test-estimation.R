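# estimation: residual construction, objective decomposition, the
# least-squares machinery against a brute-force grid oracle, fold changes.

# a tiny fabricated bundle over a handful of time points (no simulation)
tiny_bundle <- function() {
  observation_bundle(
    concentrations = data.frame(
      species = rep(c("G6P", "ATP"), each = 3),
      time_s = rep(c(10, 100, 300), 2),
      value = c(1.1, 0.9, 0.5, 2.4, 2.6, 2.5),
      sd = rep(0.05, 6)),
    fluxes = data.frame(
      reaction = rep("HXT", 3), time_s = c(10, 100, 300),
      value = c(0.6, 0.3, 0.05), sd = rep(0.03, 3)))
}

test_that("observation bundles validate and canonicalize", {
  b <- tiny_bundle()
  expect_s3_class(b, "observation_bundle")
  expect_error(observation_bundle(data.frame(species = "G6P", time_s = 500,
                                             value = 1, sd = 0.1)),
               "outside")
  expect_error(observation_bundle(data.frame(species = "G6P", time_s = 10,
                                             value = 1, sd = 0)),
               "sd")
  # empty flux table is a valid bundle with concentrations only
  b2 <- observation_bundle(b$concentrations)
  expect_equal(nrow(b2$fluxes), 0)
})

test_that("residuals vanish when simulation reproduces the data (lambda 0)", {
  b <- tiny_bundle()
  cfg <- estimation_config("HXT.Vmax", lambda = 0)
  mock_sim <- function(p) {
    blocks <- split(b$concentrations, b$concentrations$species)
    list(conc = unlist(lapply(blocks, function(d) d$value)),
         flux = b$fluxes$value)
  }
  r <- build_residuals(c("HXT.Vmax" = 1.7), cfg, b, mock_sim)
  expect_equal(max(abs(r)), 0)
  expect_equal(attr(r, "n_data"), length(r))   # no penalty block at lambda 0
})

test_that("objective decomposes exactly into data and L1 penalty terms", {
  b <- tiny_bundle()
  ref <- reference_parameters()
  mock_sim <- function(p) list(conc = rep(0, 6), flux = rep(0, 3))
  for (lam in c(0, 0.3, 2)) {
    cfg <- estimation_config(c("HXT.Vmax", "HXT.Km"), lambda = lam)
    th <- c("HXT.Vmax" = 3.1, "HXT.Km" = 0.4)
    r <- build_residuals(th, cfg, b, mock_sim)
    nd <- attr(r, "n_data")
    data_term <- sum(r[seq_len(nd)]^2)
    pen_term <- sum(r[-seq_len(nd)]^2)
    expected_pen <- lam * sum(abs(log10(th / as.numeric(ref[names(th)]))))
    expect_equal(pen_term, expected_pen, tolerance = 1e-12)
    expect_equal(sum(r^2), data_term + expected_pen, tolerance = 1e-12)
  }
})

test_that("weighted residuals: per-observable normalization and weights", {
  b <- tiny_bundle()
  cfg <- estimation_config("HXT.Vmax", weights = c(G6P = 10))
  mock_sim <- function(p) list(conc = rep(0, 6), flux = rep(0, 3))
  r <- build_residuals(c("HXT.Vmax" = 1), cfg, b, mock_sim)
  # ATP block: |obs|/max|obs| with weight 1; G6P block scaled by 10
  expect_equal(sum(r^2),
               sum((10 * c(1.1, 0.9, 0.5) / 1.1)^2) +
                 sum((c(2.4, 2.6, 2.5) / 2.6)^2) +
                 sum((c(0.6, 0.3, 0.05) / 0.6)^2), tolerance = 1e-12)
})

test_that("uniformly scaled weights scale residuals linearly (rank invariance)", {
  b <- tiny_bundle()
  mock_sim <- function(p) list(conc = rep(0, 6), flux = rep(0, 3))
  w1 <- c(G6P = 1, ATP = 2, HXT = 0.5)
  cfg1 <- estimation_config("HXT.Vmax", weights = w1)
  cfg2 <- estimation_config("HXT.Vmax", weights = 3 * w1)
  r1 <- build_residuals(c("HXT.Vmax" = 1), cfg1, b, mock_sim)
  r2 <- build_residuals(c("HXT.Vmax" = 1), cfg2, b, mock_sim)
  # costs scale by 9 exactly, so any cost-based ranking is unchanged
  expect_equal(as.numeric(r2), 3 * as.numeric(r1), tolerance = 1e-14)
})

test_that("LM least squares matches a brute-force grid oracle on a toy problem", {
  # residuals of a 2-parameter exponential model, known optimum by grid search
  set.seed(5)
  tt <- seq(0, 3, by = 0.25)
  ytrue <- 2.3 * exp(-1.1 * tt)
  yobs <- ytrue + rnorm(length(tt), 0, 0.01)
  fn <- function(x) 10^x[1] * exp(-10^x[2] * tt) - yobs
  fit <- lm_least_squares(fn, c(0, 0), lower = c(-2, -2), upper = c(2, 2))
  grid_a <- seq(log10(1.5), log10(3.5), length.out = 160)
  grid_b <- seq(log10(0.6), log10(2), length.out = 160)
  costs <- outer(grid_a, grid_b, Vectorize(function(a, b) sum(fn(c(a, b))^2)))
  expect_lte(fit$cost, min(costs) + 1e-6)
  ij <- which(costs == min(costs), arr.ind = TRUE)
  expect_equal(10^fit$par[1], 10^grid_a[ij[1]], tolerance = 0.02)
  expect_equal(10^fit$par[2], 10^grid_b[ij[2]], tolerance = 0.02)
})

test_that("empty free set returns the base parameters with pure data error", {
  b <- tiny_bundle()
  cfg <- estimation_config(character(0), lambda = 0)
  # simulator is never consulted for parameters; costs come from data alone
  fit <- suppressWarnings(fit_subset(cfg, b))
  expect_true(fit$converged)
  expect_equal(fit$param_error, 0)
  expect_equal(as.numeric(fit$par), as.numeric(calibrated_parameters()))
})

test_that("screen bookkeeping: trehalose-cycle requirement and ranking rules", {
  expect_error(combinatorial_screen(list(c("HXT")), list(NULL), tiny_bundle(),
                                    estimation_config("HXT.Vmax")),
               "trehalose")
  # ranking is by cost, ties resolved by enzyme count then id
  tab <- data.frame(subset = c("b+c", "a", "a+b"), weights = 1,
                    n_enzymes = c(2, 1, 2), cost = c(5, 5, 1),
                    converged = TRUE, error = "")
  ord <- order(is.na(tab$cost), tab$cost, tab$n_enzymes, tab$subset)
  expect_equal(tab$subset[ord], c("a+b", "a", "b+c"))
})

test_that("enzyme registry expands the trehalose cycle and rejects unknowns", {
  fr <- enzyme_free_params(c("TREHALOSE", "HXT"))
  expect_true(all(c("TPS1.Vmax", "TPS2.Vmax", "NTH1.Vmax", "HXT.Vmax") %in% fr))
  expect_error(enzyme_free_params("NOSUCH"), "registry")
})

test_that("fold-change report reproduces the adaptation table arithmetic", {
  ref <- parameter_set(c("HXT.Vmax" = 8.13, "HXK.Vmax" = 6.25,
                         "HXK.Ki_T6P" = 0.0073, "HXK.Km_GLC" = 0.35),
                       role = "reference", base = calibrated_parameters())
  est <- parameter_set(c("HXT.Vmax" = 1.70, "HXK.Vmax" = 15.75,
                         "HXK.Ki_T6P" = 0.0183, "HXK.Km_GLC" = 0.11),
                       base = calibrated_parameters())
  fc <- fold_change_report(ref, est)
  get <- function(key) fc$fold_change[paste0(fc$enzyme, ".", fc$parameter) == key]
  expect_identical(get("HXT.Vmax"), 0.21)
  expect_identical(get("HXK.Vmax"), 2.52)
  expect_identical(get("HXK.Km_GLC"), 0.31)
  expect_identical(get("HXK.Ki_T6P"), 2.51)
  # unchanged constants are omitted under the 5% rule
  expect_false("PGI.Vmax" %in% paste0(fc$enzyme, ".", fc$parameter))
  fc_all <- fold_change_report(ref, est, all = TRUE)
  expect_equal(fc_all$fold_change[paste0(fc_all$enzyme, ".",
                                         fc_all$parameter) == "PGI.Vmax"], 1)
  # a worked pair: 0.0073 -> 0.0183 gives 2.51 at two decimals
  expect_identical(round(0.0183 / 0.0073, 2), 2.51)
  # missing keys are reported as gaps, not failures
  r2 <- ref[-1]
  class(r2) <- "parameter_set"
  fc2 <- fold_change_report(r2, est)
  expect_true("HXT.Vmax" %in% attr(fc2, "missing"))
})
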
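# Synthetic observation bundles with the statistical structure of
# feast/famine metabolome/fluxome/enrichment datasets, plus the
# parameter-recovery experiment built on them.

#' Synthetic-data specification
#'
#' Defaults emulate the sampling structure of feast/famine datasets: denser
#' sampling during the first ~100 s of the cycle, multiplicative log-normal
#' noise on concentrations (CV 5%) and fluxes (CV 10%), absolute noise on
#' enrichment percentages (3 percentage points), and piecewise-linear
#' resampled flux profiles.
#'
#' @param truth ground-truth `parameter_set`
#' @param protocol a [feed_protocol()]
#' @param grid sampling times (s); default every 5 s before 100 s, every
#'   25 s afterwards
#' @param cv_conc,cv_flux multiplicative noise CVs
#' @param enrich_sd_pp absolute enrichment noise (percentage points)
#' @param seed RNG seed (fixed seed implies bitwise-reproducible bundles)
#' @param conc_species,flux_reactions,enrich_species observable selections
#' @param n_cycles unlabelled cycles before sampling
#' @param enrich enable the enrichment table (runs the labelled stage)
#' @param flux_nodes node spacing (s) of the piecewise-linear flux profiles
#' @return a `synthetic_spec`
#' @export
synthetic_spec <- function(truth = calibrated_parameters(),
                           protocol = feed_protocol(),
                           grid = c(seq(5, 95, by = 5), seq(100, 400, by = 25)),
                           cv_conc = 0.05, cv_flux = 0.10, enrich_sd_pp = 3,
                           seed = 1,
                           conc_species = c("GLCec", "GLCi", "G6P", "F6P",
                                            "FBP", "T6P", "TREc", "UDPG",
                                            "G1P", "ATP", "PYR", "PEP"),
                           flux_reactions = c("HXT", "HXK", "PFK", "PYK",
                                              "PDC", "TPS1", "NTH1",
                                              "GLY_SYNTH"),
                           enrich_species = c("G6P", "FBP", "PEP", "TREc",
                                              "GLYCOGEN"),
                           n_cycles = protocol$n_cycles, enrich = FALSE,
                           flux_nodes = 25) {
  stopifnot(cv_conc >= 0, cv_flux >= 0, enrich_sd_pp >= 0,
            all(grid >= 0), all(grid <= protocol$cycle_length))
  structure(list(truth = truth, protocol = protocol, grid = sort(unique(grid)),
                 cv_conc = cv_conc, cv_flux = cv_flux,
                 enrich_sd_pp = enrich_sd_pp, seed = seed,
                 conc_species = conc_species, flux_reactions = flux_reactions,
                 enrich_species = enrich_species, n_cycles = n_cycles,
                 enrich = enrich, flux_nodes = flux_nodes),
            class = "synthetic_spec")
}

#' Generate a synthetic observation bundle
#'
#' Simulates the chemostat steady state and `n_cycles` feast/famine cycles
#' with the true parameters (plus the enrichment stage when requested),
#' samples the final cycle at the grid, and applies seeded noise:
#' log-normal multiplicative for concentrations and fluxes (sd column is
#' CV x value), additive truncated-to-[0,100] for enrichment. Flux
#' observations are piecewise-linear resamplings of the true profiles,
#' emulating rates reconstructed from isotope data.
#'
#' @param spec a [synthetic_spec()]
#' @param rtol,atol integrator tolerances
#' @param truth_trajectory optional precomputed `ff_trajectory` of the truth
#'   (skips the chemostat/cycle stages; used for cheap replicate noise draws)
#' @return an `observation_bundle` (provenance "synthetic") with attribute
#'   `truth_trajectory`
#' @export
generate_bundle <- function(spec, rtol = 1e-7, atol = 1e-9,
                            truth_trajectory = NULL) {
  traj <- truth_trajectory
  if (is.null(traj)) {
    ss <- tryCatch(
      run_chemostat(spec$truth, spec$protocol, rtol = rtol, atol = atol),
      error = function(e) stop("synthetic generation failed in chemostat stage: ",
                               conditionMessage(e)))
    traj <- tryCatch(
      run_cycles(ss, spec$truth, spec$protocol, n_cycles = spec$n_cycles,
                 out_dt = 2, keep = "last", rtol = rtol, atol = atol),
      error = function(e) stop("synthetic generation failed in cycle stage: ",
                               conditionMessage(e)))
  }
  set.seed(spec$seed)
  sdlog_c <- sqrt(log(1 + spec$cv_conc^2))
  sdlog_f <- sqrt(log(1 + spec$cv_flux^2))
  grab_state <- function(sp) approx(traj$time, traj$states[, sp],
                                    xout = spec$grid, rule = 2)$y
  conc <- do.call(rbind, lapply(spec$conc_species, function(sp) {
    true <- grab_state(sp)
    noisy <- true * exp(rnorm(length(true), 0, sdlog_c))
    data.frame(species = sp, time_s = spec$grid, value = noisy,
               sd = pmax(spec$cv_conc * noisy, 1e-9),
               stringsAsFactors = FALSE)
  }))
  nodes <- seq(0, spec$protocol$cycle_length, by = spec$flux_nodes)
  flux <- do.call(rbind, lapply(spec$flux_reactions, function(rx) {
    at_nodes <- approx(traj$time, traj$fluxes[, rx], xout = nodes, rule = 2)$y
    pw <- approx(nodes, at_nodes, xout = spec$grid)$y   # piecewise-linear profile
    noisy <- pw * exp(rnorm(length(pw), 0, sdlog_f))
    data.frame(reaction = rx, time_s = spec$grid, value = noisy,
               sd = pmax(spec$cv_flux * abs(noisy), 1e-9),
               stringsAsFactors = FALSE)
  }))
  enr <- NULL
  if (spec$enrich) {
    endstate <- model_state(traj$states[nrow(traj$states), model_species()])
    er <- tryCatch(
      simulate_enrichment(endstate, spec$truth, spec$protocol,
                          rtol = rtol, atol = atol),
      error = function(e) stop("synthetic generation failed in enrichment stage: ",
                               conditionMessage(e)))
    enr <- do.call(rbind, lapply(spec$enrich_species, function(sp) {
      true <- approx(er$time, er$enrichment[, sp], xout = spec$grid, rule = 2)$y
      noisy <- pmin(pmax(true + rnorm(length(true), 0, spec$enrich_sd_pp), 0), 100)
      data.frame(species = sp, time_s = spec$grid, value = noisy,
                 sd = rep(max(spec$enrich_sd_pp, 1e-9), length(true)),
                 stringsAsFactors = FALSE)
    }))
  }
  bundle <- observation_bundle(conc, flux, enr, provenance = "synthetic",
                               cycle_length = spec$protocol$cycle_length)
  attr(bundle, "truth_trajectory") <- traj
  bundle
}

#' Parameter-recovery experiment
#'
#' For each seed: generate a synthetic bundle from the ground truth, fit the
#' free subset starting from the reference values, and report per-parameter
#' relative errors. Per-seed failures are tolerated and aggregated.
#'
#' @param spec a [synthetic_spec()] (its `truth` carries the recoverable
#'   signal, e.g. the adapted transport/phosphorylation constants)
#' @param free character vector of free parameter keys; the default releases
#'   the structurally identifiable transport/phosphorylation constants
#'   (HXT Vmax and Km, HXK/GLK Vmax). HXK Km_GLC and Ki_T6P are excluded by
#'   default: at the Table-backed Vmax the enzyme runs far below saturation,
#'   so only flux ratios involving them are observable from cycle data.
#' @param n_seeds number of independent bundles
#' @param lambda regularization factor of the second estimation step (the
#'   first step is unregularized; the second starts from its solution)
#' @param config_base an `estimation_config` template (free field replaced)
#' @param protocol a [feed_protocol()]
#' @return a `recovery_report`: `per_seed` (relative errors), `summary`
#'   (median/quantiles per parameter), `failures`
#' @export
recovery_experiment <- function(spec,
                                free = c("HXT.Vmax", "HXT.Km", "HXK.Vmax"),
                                n_seeds = 10, lambda = 0.1,
                                config_base = NULL,
                                protocol = spec$protocol) {
  if (is.null(config_base))
    config_base <- estimation_config(free, base = spec$truth,
                                     n_cycles_fit = min(2, spec$n_cycles),
                                     max_iter = 15)
  truth_vals <- as.numeric(spec$truth[free])
  per_seed <- list()
  failures <- 0L
  for (s in seq_len(n_seeds)) {
    sp <- spec; sp$seed <- spec$seed + s - 1
    res <- tryCatch({
      bundle <- generate_bundle(sp)
      cfg <- config_base
      cfg$free <- free
      cfg$seed <- sp$seed
      fit <- fit_subset(cfg, bundle, protocol)
      if (lambda > 0) {
        cfg2 <- cfg
        cfg2$lambda <- lambda
        cfg2$start <- fit$estimates
        cfg2$max_iter <- max(8L, cfg$max_iter %/% 2L)
        fit <- fit_subset(cfg2, bundle, protocol)
      }
      est <- as.numeric(fit$estimates[free])
      data.frame(seed = sp$seed, parameter = free, truth = truth_vals,
                 estimate = est, rel_error = abs(est - truth_vals) / truth_vals,
                 converged = fit$converged, stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else
      per_seed[[length(per_seed) + 1L]] <- res
  }
  if (!length(per_seed)) stop("all recovery seeds failed")
  tab <- do.call(rbind, per_seed)
  summary <- do.call(rbind, lapply(split(tab, tab$parameter), function(d)
    data.frame(parameter = d$parameter[1],
               truth = d$truth[1],
               median_estimate = median(d$estimate),
               median_rel_error = median(d$rel_error),
               q90_rel_error = unname(quantile(d$rel_error, 0.9)),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(per_seed = tab, summary = summary, failures = failures,
                 free = free), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$summary)
  invisible(x)
}
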
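# Robustness and feasibility sampling: parameter-perturbation ensembles and
# the passive-transport (no glucose-sensing) feasibility scan.

#' Ensemble specification
#'
#' @param n number of samples
#' @param range relative perturbation half-width for uniform sampling
#'   (0.10 = +/-10%)
#' @param decades half-width in log10 decades for the log-uniform scan
#' @param seed RNG seed
#' @param scope `"all"` constants or `"HXT"` (transporter constants only)
#' @return an `ensemble_spec`
#' @export
ensemble_spec <- function(n = 50, range = 0.10, decades = 3, seed = 1,
                          scope = c("all", "HXT")) {
  stopifnot(n >= 1, range > 0, decades > 0)
  structure(list(n = n, range = range, decades = decades, seed = seed,
                 scope = match.arg(scope)), class = "ensemble_spec")
}

.perturbable <- function(scope) {
  keys <- model_parameters()
  keys <- setdiff(keys, c("HXT.sensing"))   # structural flag, not a constant
  if (scope == "HXT") keys <- c("HXT.Vmax", "HXT.Km", "HXT.Ki")
  keys
}

#' Parameter-perturbation ensemble
#'
#' Draws `n` parameter sets uniformly in `[1-r, 1+r]` times each constant
#' (seeded), simulates `n_cycles` feast/famine cycles per sample from the
#' shipped steady state, and summarizes the per-time standard deviation of
#' every species and flux across the ensemble, normalized by each profile's
#' scale (its maximal absolute ensemble-mean value over the cycle). Failed samples
#' are counted and excluded.
#'
#' @param p base `parameter_set`
#' @param spec an [ensemble_spec()]
#' @param protocol a [feed_protocol()]
#' @param init initial state
#' @param n_cycles cycles per sample (the last is analyzed)
#' @param out_dt output grid (s)
#' @param rtol,atol,max_steps integrator controls
#' @return an `ensemble_result`: `dispersion` (per-variable median relative
#'   SD), `failures`, `n_ok`, the sampled factors, and summary matrices
#' @export
perturb_ensemble <- function(p, spec, protocol = feed_protocol(),
                             init = shipped_steady_state(), n_cycles = 2,
                             out_dt = 10, rtol = 1e-6, atol = 1e-8,
                             max_steps = 60000L) {
  validate_parameter_set(p)
  keys <- .perturbable(spec$scope)
  set.seed(spec$seed)
  factors <- matrix(runif(spec$n * length(keys), 1 - spec$range, 1 + spec$range),
                    spec$n, length(keys), dimnames = list(NULL, keys))
  state_traces <- list(); flux_traces <- list()
  failures <- 0L
  tgrid <- NULL
  for (i in seq_len(spec$n)) {
    pi <- p
    pi[keys] <- as.numeric(p[keys]) * factors[i, ]
    traj <- tryCatch(
      run_cycles(init, pi, protocol, n_cycles = n_cycles, out_dt = out_dt,
                 keep = "last", rtol = rtol, atol = atol,
                 max_steps = max_steps),
      error = function(e) NULL)
    if (is.null(traj)) { failures <- failures + 1L; next }
    tgrid <- traj$time
    state_traces[[length(state_traces) + 1L]] <- traj$states
    flux_traces[[length(flux_traces) + 1L]] <- traj$fluxes
  }
  n_ok <- length(state_traces)
  if (!n_ok) stop("all ensemble samples failed")
  rel_sd <- function(traces) {
    arr <- simplify2array(traces)                 # time x var x sample
    m <- apply(arr, c(1, 2), mean)
    s <- apply(arr, c(1, 2), sd)
    # normalize by the profile scale (max |mean| over the cycle), not the
    # pointwise mean: famine-phase values near zero would otherwise blow up
    # the relative measure for every intrinsically transient variable
    scale <- pmax(apply(abs(m), 2, max), 1e-9)
    rs <- sweep(s, 2, scale, "/")
    apply(rs, 2, median)                          # median over time per variable
  }
  disp_state <- rel_sd(state_traces)
  disp_flux <- rel_sd(flux_traces)
  structure(list(
    dispersion = data.frame(
      variable = c(names(disp_state), names(disp_flux)),
      kind = c(rep("concentration", length(disp_state)),
               rep("flux", length(disp_flux))),
      median_rel_sd = c(disp_state, disp_flux),
      row.names = NULL, stringsAsFactors = FALSE),
    time = tgrid, failures = failures, n_ok = n_ok, factors = factors,
    spec = spec), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result: %d ok, %d failed, r=%.0f%%>\n",
              x$n_ok, x$failures, 100 * x$spec$range))
  invisible(x)
}

#' Default extracellular glucose trace for the feasibility scan
#'
#' One converged calibrated cycle's extracellular glucose profile (residual
#' about 0.1 g/L, maximum about 0.45 g/L).
#' @param p parameter set used to generate the trace
#' @param protocol a [feed_protocol()]
#' @param n_cycles cycles to converge before recording
#' @return data.frame (`time_s`, `value_mM`)
#' @export
reference_glcec_trace <- function(p = calibrated_parameters(),
                                  protocol = feed_protocol(), n_cycles = 5) {
  traj <- run_cycles(shipped_steady_state(), p, protocol,
                     n_cycles = n_cycles, out_dt = 2, keep = "last",
                     rtol = 1e-7, atol = 1e-9)
  data.frame(time_s = traj$time, value_mM = traj$states[, "GLCec"])
}

#' Passive-transport feasibility scan for HXT kinetics
#'
#' With the extracellular glucose trace fixed to a converged cycle profile
#' and glucose sensing off, samples HXT constants (Vmax, Km, Ki)
#' log-uniformly over +/- `decades` around the estimated values,
#' re-simulates the intracellular model against the clamped trace, and
#' records the net uptake rate at 20 s and at 400 s per sample. The
#' feasibility question: does any passive sample reach an uptake of at
#' least `target` at 20 s while staying at or below `eps` at 400 s? The
#' sensing-on calibrated model is evaluated as the reference point.
#'
#' @param p calibrated `parameter_set` (scan centre)
#' @param spec an [ensemble_spec()] (`n`, `decades`, `seed` used)
#' @param protocol a [feed_protocol()]
#' @param glcec_trace forced GLCec profile, see [reference_glcec_trace()]
#' @param target uptake threshold at 20 s (mM/s)
#' @param eps "almost zero" end-of-cycle uptake threshold (mM/s)
#' @param init initial intracellular state
#' @param rtol,atol,max_steps integrator controls
#' @return an `hxt_scan_result`: `samples` data.frame (constants, uptake at
#'   20/400 s, ok flag), `sensing_on` reference pair, `feasible` verdict
#' @export
hxt_feasibility_scan <- function(p = calibrated_parameters(),
                                 spec = ensemble_spec(n = 200, decades = 3),
                                 protocol = feed_protocol(),
                                 glcec_trace = NULL,
                                 target = 0.72, eps = 0.02,
                                 init = shipped_steady_state(),
                                 rtol = 1e-6, atol = 1e-8,
                                 max_steps = 60000L) {
  if (is.null(glcec_trace))
    glcec_trace <- reference_glcec_trace(p, protocol)
  keys <- c("HXT.Vmax", "HXT.Km", "HXT.Ki")
  set.seed(spec$seed)
  draws <- matrix(10^runif(spec$n * length(keys), -spec$decades, spec$decades),
                  spec$n, length(keys), dimnames = list(NULL, keys))
  tabs <- glycogen_tables()
  n_settle <- 2L   # clamped cycles before the measured cycle
  run_one <- function(pi) {
    env <- phase_env(protocol, "batch", cycle_t0 = 0, tables = tabs,
                     clamp = glcec_trace)
    cl <- protocol$cycle_length
    # the clamp trace is periodic; settle the intracellular state first
    times <- seq(0, (n_settle + 1) * cl, by = 2)
    r <- integrate_model(as.numeric(init), times, pi, env,
                         rtol = rtol, atol = atol, max_steps = max_steps)
    if (!r$ok) return(NULL)
    t20 <- n_settle * cl + 20
    v20 <- cpp_fluxes(r$y[which.min(abs(times - t20)), ], t20,
                      as.numeric(pi), env)[["HXT"]]
    v400 <- cpp_fluxes(r$y[nrow(r$y), ], (n_settle + 1) * cl,
                       as.numeric(pi), env)[["HXT"]]
    c(v20 = v20, v400 = v400)
  }
  rows <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    pi <- p
    pi[keys] <- as.numeric(p[keys]) * draws[i, ]
    pi[["HXT.sensing"]] <- 0
    u <- run_one(pi)
    rows[[i]] <- data.frame(
      Vmax = pi[["HXT.Vmax"]], Km = pi[["HXT.Km"]], Ki = pi[["HXT.Ki"]],
      uptake_20s = if (is.null(u)) NA_real_ else u[["v20"]],
      uptake_400s = if (is.null(u)) NA_real_ else u[["v400"]],
      ok = !is.null(u))
  }
  samples <- do.call(rbind, rows)
  son <- run_one(p)   # calibrated, sensing on
  hits <- with(samples, ok & uptake_20s >= target & uptake_400s <= eps)
  structure(list(samples = samples,
                 sensing_on = c(uptake_20s = unname(son["v20"]),
                                uptake_400s = unname(son["v400"])),
                 feasible = any(hits, na.rm = TRUE),
                 n_failed = sum(!samples$ok),
                 target = target, eps = eps, spec = spec),
            class = "hxt_scan_result")
}

#' @export
print.hxt_scan_result <- function(x, ...) {
  cat(sprintf(paste0("<hxt_scan: %d samples (%d failed), passive feasible=%s; ",
                     "sensing-on pair (%.3f, %.4f) mM/s>\n"),
              nrow(x$samples), x$n_failed, x$feasible,
              x$sensing_on[["uptake_20s"]], x$sensing_on[["uptake_400s"]]))
  invisible(x)
}
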
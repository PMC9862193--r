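# Shared fixtures, memoised across test files (testthat runs all files in
# one process; heavy simulations are paid for once).

.ff_cache <- new.env(parent = emptyenv())

ff_cached <- function(name, expr) {
  if (is.null(.ff_cache[[name]])) assign(name, force(expr), envir = .ff_cache)
  .ff_cache[[name]]
}

fx_calib <- function() ff_cached("calib", calibrated_parameters())
fx_ref <- function() ff_cached("ref", reference_parameters())
fx_proto <- function() ff_cached("proto", feed_protocol())

fx_steady <- function() ff_cached("steady", run_chemostat(fx_calib(), fx_proto()))

# the shipped 20-cycle simulation (all cycles recorded), with wall time
fx_traj20 <- function() ff_cached("traj20", {
  t0 <- Sys.time()
  traj <- run_cycles(fx_steady(), fx_calib(), fx_proto(), n_cycles = 20,
                     out_dt = 2, keep = "all")
  attr(traj, "wall_s") <- as.numeric(Sys.time() - t0, units = "secs")
  traj
})

fx_endstate <- function() ff_cached("endstate", {
  traj <- fx_traj20()
  model_state(traj$states[nrow(traj$states), model_species()])
})

fx_enrich <- function() ff_cached("enrich",
  simulate_enrichment(fx_endstate(), fx_calib(), fx_proto()))

# a random admissible state away from the steady state (positive, bounded)
fx_random_state <- function(seed) {
  set.seed(seed)
  ss <- as.numeric(shipped_steady_state())
  names(ss) <- model_species()
  y <- ss * exp(rnorm(length(ss), 0, 0.5))
  y["VOL"] <- 1
  y
}

fx_env <- function(phase = "chemostat", ...) phase_env(fx_proto(), phase, ...)
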
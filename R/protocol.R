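# Feed protocol and the three-stage simulation: chemostat steady state,
# block-wise feast/famine cycles with broth-volume dynamics, and helpers.

#' Feed protocol for chemostat and feast/famine operation
#'
#' Defaults reproduce the shipped calibrated configuration: dilution rate
#' 0.1 h^-1, 400-s cycles with a 20-s feed window at 20-fold the chemostat
#' feed concentration (same average substrate supply), constant outflow
#' removing the feed volume by 260 s, 20 cycles.
#'
#' @param dilution_rate chemostat dilution rate (1/h)
#' @param cs_chem chemostat feed glucose concentration (g/L)
#' @param biomass biomass concentration (g dry weight per L broth), held
#'   constant within cycles
#' @param cycle_length cycle length (s)
#' @param feed_window feed duration at cycle start (s)
#' @param feed_multiplier feed concentration multiplier vs. chemostat
#' @param outflow_end time by which the fed volume has been withdrawn (s)
#' @param n_cycles number of repetitive cycles
#' @param residence_pre chemostat residence times before the regime
#' @param volume broth volume (L)
#' @param vacuole_fraction vacuolar volume as a fraction of cytosolic volume
#' @param label_fraction 13C-labelled fraction of feed glucose during the
#'   enrichment stage
#' @return an object of class `feed_protocol`
#' @export
feed_protocol <- function(dilution_rate = NULL, cs_chem = NULL, biomass = NULL,
                          cycle_length = NULL, feed_window = NULL,
                          feed_multiplier = NULL, outflow_end = NULL,
                          n_cycles = NULL, residence_pre = NULL, volume = NULL,
                          vacuole_fraction = NULL, label_fraction = NULL) {
  d <- jsonlite::read_json(.extdata("protocol_default.json"), simplifyVector = TRUE)
  pr <- list(
    dilution_rate = dilution_rate %||% d$dilution_rate,
    cs_chem = cs_chem %||% d$cs_chem_gL,
    biomass = biomass %||% d$biomass_gdw_L,
    cycle_length = cycle_length %||% d$cycle_length,
    feed_window = feed_window %||% d$feed_window,
    feed_multiplier = feed_multiplier %||% d$feed_multiplier,
    outflow_end = outflow_end %||% d$outflow_end,
    n_cycles = n_cycles %||% d$n_cycles,
    residence_pre = residence_pre %||% d$residence_pre,
    volume = volume %||% d$broth_volume_L,
    vacuole_fraction = vacuole_fraction %||% d$vacuole_fraction,
    label_fraction = label_fraction %||% d$label_fraction
  )
  stopifnot(pr$dilution_rate > 0, pr$feed_multiplier > 0,
            pr$feed_window < pr$outflow_end,
            pr$outflow_end <= pr$cycle_length,
            pr$n_cycles >= 1, pr$volume > 0, pr$biomass > 0,
            pr$label_fraction >= 0, pr$label_fraction <= 1)
  pr$D_s <- pr$dilution_rate / 3600                    # 1/s
  pr$cs_mM <- glc_gL_to_mM(pr$cs_chem)
  pr$phi <- pr$biomass * BIOMASS_VOLUME_FRACTION       # L cytosol / L broth
  structure(pr, class = "feed_protocol")
}

#' @export
print.feed_protocol <- function(x, ...) {
  cat(sprintf(paste0("<feed_protocol D=%.3g/h, feed %.3g g/L x%g for %gs, ",
                     "cycle %gs, outflow to %gs, %d cycles>\n"),
              x$dilution_rate, x$cs_chem, x$feed_multiplier, x$feed_window,
              x$cycle_length, x$outflow_end, x$n_cycles))
  invisible(x)
}

#' Shipped glycogen flux interpolation tables
#'
#' Piecewise-linear base fluxes for glycogen synthesis and degradation over
#' the 400-s cycle, calibrated to turn over roughly 8% of the substrate
#' supply with synthesis concentrated in the feast phase.
#' @return list with data.frames `synthesis`, `degradation`
#'   (columns `time_s`, `flux_mM_per_s`)
#' @export
glycogen_tables <- function() {
  list(synthesis = read.csv(.extdata("glycogen_synthesis.csv")),
       degradation = read.csv(.extdata("glycogen_degradation.csv")))
}

#' Shipped chemostat steady state of the calibrated model
#' @return named state vector (class `model_state`)
#' @export
shipped_steady_state <- function() {
  s <- unlist(jsonlite::read_json(.extdata("steady_state_calibrated.json"),
                                  simplifyVector = TRUE))
  model_state(s[model_species()])
}

#' Construct a model state
#' @param x named numeric vector over [model_species()]
#' @return class `model_state`
#' @export
model_state <- function(x) {
  x <- unlist(x)
  missing_sp <- setdiff(model_species(), names(x))
  if (length(missing_sp))
    stop("state lacks species: ", paste(missing_sp, collapse = ", "))
  y <- x[model_species()]
  if (any(y < 0)) stop("negative concentration in state")
  if (y[["VOL"]] <= 0) stop("non-positive broth volume")
  structure(y, class = "model_state")
}

#' Phase environment for the integrator
#'
#' Bundles the per-phase constants: feed/outflow rates, feed concentration,
#' compartment geometry, glycogen forcing mode, label fraction, and an
#' optional extracellular-glucose clamp trace.
#'
#' @param protocol a [feed_protocol()]
#' @param phase one of `"chemostat"`, `"feed"`, `"outflow"`, `"batch"`
#' @param cycle_t0 absolute time of the current cycle start (s)
#' @param tables glycogen tables, see [glycogen_tables()]
#' @param lfeed labelled fraction of the feed glucose
#' @param clamp optional data.frame (`time_s`, `value_mM`) forcing GLCec
#' @return list consumed by the compiled integrator
#' @export
phase_env <- function(protocol, phase = c("chemostat", "feed", "outflow", "batch"),
                      cycle_t0 = 0, tables = glycogen_tables(), lfeed = 0,
                      clamp = NULL) {
  phase <- match.arg(phase)
  fin_chem <- protocol$D_s * protocol$volume
  dvol <- fin_chem * protocol$feed_window
  env <- switch(phase,
    chemostat = list(fin = fin_chem, fout = fin_chem,
                     cfeed = protocol$cs_mM, gly_mode = 0L),
    feed = list(fin = fin_chem, fout = 0,
                cfeed = protocol$feed_multiplier * protocol$cs_mM, gly_mode = 1L),
    outflow = list(fin = 0,
                   fout = dvol / (protocol$outflow_end - protocol$feed_window),
                   cfeed = 0, gly_mode = 1L),
    batch = list(fin = 0, fout = 0, cfeed = 0, gly_mode = 1L)
  )
  env$phi <- protocol$phi
  env$fvac <- protocol$vacuole_fraction
  env$lfeed <- lfeed
  env$gly_syn_t <- tables$synthesis$time_s
  env$gly_syn_v <- tables$synthesis$flux_mM_per_s
  env$gly_deg_t <- tables$degradation$time_s
  env$gly_deg_v <- tables$degradation$flux_mM_per_s
  env$cycle_len <- protocol$cycle_length
  env$cycle_t0 <- cycle_t0
  env$clamp_t <- if (is.null(clamp)) numeric(0) else clamp$time_s
  env$clamp_v <- if (is.null(clamp)) numeric(0) else clamp$value_mM
  env
}

#' Integrate the model over a time span
#'
#' Thin wrapper around the compiled Rosenbrock (RODAS3) integrator.
#' @param y0 state vector (totals, optionally followed by the labelled block)
#' @param times output times (first element is the initial time)
#' @param p a `parameter_set`
#' @param env a [phase_env()]
#' @param labelled integrate the 13C-labelled block too
#' @param rtol,atol integration tolerances
#' @param max_steps step budget before aborting
#' @return list with `y` (times x states matrix), `ok`, `message`, counters
#' @export
integrate_model <- function(y0, times, p, env, labelled = FALSE,
                            rtol = 1e-8, atol = 1e-10, max_steps = 200000L) {
  r <- cpp_integrate(as.numeric(y0), as.numeric(times), as.numeric(p), env,
                     rtol, atol, labelled, 0.0, 1e-7, 1e-4, as.integer(max_steps))
  nm <- model_species()
  if (labelled) nm <- c(nm, paste0(carbon_species(), "_L"))
  colnames(r$y) <- nm
  r
}

.moiety_refs <- function(y) {
  c(adenylate = sum(y[c("ATP", "ADP", "AMP")]), nicotinamide = sum(y[c("NAD", "NADH")]))
}

#' Chemostat steady state
#'
#' Integrates the chemostat phase from `init` over `settle` seconds, then
#' polishes the state with damped Newton iteration on the reduced system
#' (moiety totals and broth volume eliminated), and verifies the residual.
#' Oscillatory parameter sets whose steady state is an unstable focus are
#' still resolved by the Newton stage.
#'
#' @param p a `parameter_set`
#' @param protocol a [feed_protocol()]
#' @param init initial state (default: shipped calibrated steady state)
#' @param settle pre-integration horizon (s)
#' @param tol steady-state residual tolerance (mM/s)
#' @param rtol,atol integration tolerances
#' @param tables glycogen flux tables (see [glycogen_tables()])
#' @return a `model_state` with attributes `residual` and `fluxes`
#' @export
run_chemostat <- function(p, protocol = feed_protocol(),
                          init = shipped_steady_state(), settle = 20000,
                          tol = 1e-6, rtol = 1e-7, atol = 1e-9,
                          tables = glycogen_tables()) {
  validate_parameter_set(p)
  env <- phase_env(protocol, "chemostat", tables = tables)
  y <- as.numeric(init)
  if (settle > 0) {
    r <- integrate_model(y, c(0, settle), p, env, rtol = rtol, atol = atol)
    if (r$ok) y <- r$y[nrow(r$y), ]   # a failed settle (oscillation) is fine
  }
  sp <- model_species()
  iAMP <- match("AMP", sp); iNADH <- match("NADH", sp); iVOL <- match("VOL", sp)
  iATP <- match("ATP", sp); iADP <- match("ADP", sp); iNAD <- match("NAD", sp)
  Atot <- y[iATP] + y[iADP] + y[iAMP]; Ntot <- y[iNAD] + y[iNADH]
  free <- setdiff(seq_along(sp), c(iAMP, iNADH, iVOL))
  expand <- function(x) {
    z <- numeric(length(sp)); z[free] <- x
    z[iAMP] <- Atot - z[iATP] - z[iADP]
    z[iNADH] <- Ntot - z[iNAD]
    z[iVOL] <- as.numeric(init)[iVOL]
    z
  }
  fres <- function(x) cpp_rhs(expand(x), 0, as.numeric(p), env)[free]
  # damped Gauss-Newton (Levenberg-Marquardt on the residual): plain Newton
  # overshoots badly in this ill-conditioned system (state scales span seven
  # orders of magnitude); Marquardt damping handles that and also tolerates
  # frozen pools with all-zero Jacobian rows
  x <- y[free]
  f0 <- fres(x)
  mu <- 1e-8
  for (it in seq_len(200)) {
    if (max(abs(f0)) < 1e-12) break
    J <- matrix(0, length(x), length(x))
    for (j in seq_along(x)) {
      dx <- 1e-7 * abs(x[j]) + 1e-9   # floor keeps probes above solver noise
      xp <- x; xp[j] <- xp[j] + dx
      J[, j] <- (fres(xp) - f0) / dx
    }
    cn <- sqrt(colSums(J^2)) + 1e-12
    improved <- FALSE
    for (tries in 1:30) {
      # QR on the damped augmented system: the normal equations would square
      # an already severe condition number (state scales span ~7 decades)
      Jaug <- rbind(J, sqrt(mu) * diag(cn, length(x)))
      step <- tryCatch(qr.solve(Jaug, c(-f0, numeric(length(x)))),
                       error = function(e) NULL)
      if (!is.null(step)) {
        xn <- pmax(x + as.numeric(step), 1e-12)
        fn <- fres(xn)
        if (all(is.finite(fn)) && sum(fn^2) < sum(f0^2)) {
          x <- xn; f0 <- fn
          mu <- max(mu / 4, 1e-12)
          improved <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!improved) break
  }
  yss <- expand(x)
  resid <- max(abs(cpp_rhs(yss, 0, as.numeric(p), env)))
  if (!is.finite(resid) || resid > tol)
    stop(sprintf("no steady state within horizon (worst residual %.3g mM/s)", resid))
  if (any(yss[-iVOL] < 0) || any(yss[match(c("GLCi", "G6P", "ATP"), sp)] <= 0))
    stop("steady state has non-positive concentrations")
  names(yss) <- sp
  st <- model_state(yss)
  attr(st, "residual") <- resid
  attr(st, "fluxes") <- cpp_fluxes(yss, 0, as.numeric(p), env)
  st
}

#' Simulate repetitive feast/famine cycles
#'
#' Runs `n_cycles` cycles of block-wise feeding from `state`, restarting the
#' integrator at every phase switch (feed / outflow / batch) so no solver
#' step straddles a discontinuity. The feed delivers the same average
#' substrate as the chemostat; the outflow phase removes exactly the fed
#' volume at constant rate, so the broth volume closes each cycle by
#' construction.
#'
#' @param state initial `model_state` (typically from [run_chemostat()])
#' @param p a `parameter_set`
#' @param protocol a [feed_protocol()]
#' @param n_cycles number of cycles (default from protocol)
#' @param out_dt output grid spacing within the recorded cycles (s)
#' @param keep `"last"` records the final cycle only (plus all cycle-end
#'   states); `"all"` records every cycle
#' @param labelled carry the 13C-labelled block (requires `lstate`)
#' @param lstate labelled initial block (mM), default all-zero
#' @param lfeed labelled fraction of feed glucose
#' @param rtol,atol,max_steps integrator controls
#' @param tables glycogen flux tables (see [glycogen_tables()])
#' @return an `ff_trajectory`: list with `time` (cycle time, s), `cycle`,
#'   `states`, `fluxes` matrices, `cycle_ends` (state at each cycle end),
#'   `params`, `protocol`
#' @export
run_cycles <- function(state, p, protocol = feed_protocol(),
                       n_cycles = protocol$n_cycles, out_dt = 2,
                       keep = c("last", "all"), labelled = FALSE,
                       lstate = NULL, lfeed = protocol$label_fraction,
                       rtol = 1e-8, atol = 1e-10, max_steps = 200000L,
                       tables = glycogen_tables()) {
  keep <- match.arg(keep)
  validate_parameter_set(p)
  tabs <- tables
  y <- as.numeric(state)
  if (labelled) {
    if (is.null(lstate)) lstate <- setNames(numeric(length(carbon_species())),
                                            carbon_species())
    y <- c(y, as.numeric(lstate))
  }
  nsp <- length(model_species())
  cl <- protocol$cycle_length
  grid_for <- function(a, b) {
    g <- seq(a, b, by = out_dt)
    if (tail(g, 1) < b) g <- c(g, b)
    g
  }
  rows_t <- c(); rows_cyc <- c(); rows_y <- NULL
  cycle_ends <- matrix(NA_real_, n_cycles, length(y))
  vol_err <- numeric(n_cycles)
  t0 <- 0
  for (cyc in seq_len(n_cycles)) {
    record <- keep == "all" || cyc == n_cycles
    v0 <- y[match("VOL", model_species())]
    for (ph in list(c("feed", 0, protocol$feed_window),
                    c("outflow", protocol$feed_window, protocol$outflow_end),
                    c("batch", protocol$outflow_end, cl))) {
      env <- phase_env(protocol, ph[[1]], cycle_t0 = t0, tables = tabs,
                       lfeed = if (labelled) lfeed else 0)
      times <- t0 + grid_for(as.numeric(ph[[2]]), as.numeric(ph[[3]]))
      r <- integrate_model(y, times, p, env, labelled = labelled,
                           rtol = rtol, atol = atol, max_steps = max_steps)
      if (!r$ok)
        stop(sprintf("integration failed in cycle %d phase %s: %s",
                     cyc, ph[[1]], r$message))
      y <- r$y[nrow(r$y), ]
      if (record) {
        sel <- seq_len(nrow(r$y) - 1L)           # avoid duplicating switch points
        rows_t <- c(rows_t, times[sel] - t0)
        rows_cyc <- c(rows_cyc, rep(cyc, length(sel)))
        rows_y <- rbind(rows_y, r$y[sel, , drop = FALSE])
      }
    }
    if (y[match("VOL", model_species())] < 0) stop("negative broth volume")
    vol_err[cyc] <- abs(y[match("VOL", model_species())] - v0) / v0
    cycle_ends[cyc, ] <- y
    t0 <- t0 + cl
  }
  # close the recorded trajectory with the final state at t = cycle length
  rows_t <- c(rows_t, cl)
  rows_cyc <- c(rows_cyc, n_cycles)
  rows_y <- rbind(rows_y, y)
  colnames(rows_y) <- if (labelled)
    c(model_species(), paste0(carbon_species(), "_L")) else model_species()
  # flux trace on the recorded grid (glycogen forcing uses cycle time)
  envf <- phase_env(protocol, "batch", cycle_t0 = 0, tables = tabs)
  fl <- t(vapply(seq_along(rows_t), function(i)
    cpp_fluxes(rows_y[i, seq_len(nsp)], rows_t[i], as.numeric(p), envf),
    numeric(length(model_reactions()))))
  colnames(fl) <- model_reactions()
  structure(list(time = rows_t, cycle = rows_cyc, states = rows_y,
                 fluxes = fl, cycle_ends = cycle_ends, volume_error = vol_err,
                 labelled = labelled, params = p, protocol = protocol),
            class = "ff_trajectory")
}

#' @export
print.ff_trajectory <- function(x, ...) {
  cat(sprintf("<ff_trajectory: %d recorded points, cycles %s, labelled=%s>\n",
              length(x$time), paste(range(x$cycle), collapse = "-"),
              x$labelled))
  invisible(x)
}

#' Tidy data.frame view of a trajectory
#' @param x an `ff_trajectory`
#' @param row.names,optional,... ignored (S3 signature)
#' @export
as.data.frame.ff_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  wide <- cbind(data.frame(time_s = x$time, cycle = x$cycle), x$states, x$fluxes)
  vars <- c(colnames(x$states), colnames(x$fluxes))
  out <- do.call(rbind, lapply(vars, function(v) {
    data.frame(time_s = x$time, cycle = x$cycle, variable = v,
               value = wide[[v]],
               unit = if (v %in% colnames(x$fluxes)) "mM/s" else
                 if (v == "VOL") "L" else "mM",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-cycle summary metrics
#'
#' Maximum, minimum and time-of-maximum per species and per flux over the
#' recorded (final) cycle, the ratio of maximal trehalose-synthesis flux
#' (TPS1, the committed G6P+UDPG step) to maximal hexokinase flux, and a
#' cumulative CO2 proxy integrating decarboxylation stoichiometry (1 CO2 per
#' PDC turnover, 3 per pyruvate-sink turnover).
#' @param traj an `ff_trajectory`
#' @return list with `species` and `fluxes` data.frames, `ratios`,
#'   `co2_proxy_mM` and `limit_cycle` (RMS of consecutive cycle-end state
#'   differences, aggregate relative)
#' @export
cycle_summary <- function(traj) {
  last_cycle <- max(traj$cycle)
  sel <- traj$cycle == last_cycle
  tt <- traj$time[sel]
  summarize <- function(m) {
    data.frame(
      variable = colnames(m),
      max = apply(m[sel, , drop = FALSE], 2, max),
      min = apply(m[sel, , drop = FALSE], 2, min),
      t_max = tt[apply(m[sel, , drop = FALSE], 2, which.max)],
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  sp <- summarize(traj$states)
  fl <- summarize(traj$fluxes)
  ratios <- list(
    trehalose_vs_hxk_pct =
      100 * max(traj$fluxes[sel, "TPS1"]) / max(traj$fluxes[sel, "HXK"])
  )
  co2_rate <- traj$fluxes[sel, "PDC"] + 3 * traj$fluxes[sel, "sink_PYR"]
  co2 <- sum(0.5 * (head(co2_rate, -1) + tail(co2_rate, -1)) * diff(tt))
  nce <- nrow(traj$cycle_ends)
  lc <- if (nce >= 2) {
    a <- traj$cycle_ends[nce - 1, ]; b <- traj$cycle_ends[nce, ]
    scale <- pmax(abs(a), 1e-8)
    sqrt(mean(((b - a) / scale)^2))
  } else NA_real_
  list(species = sp, fluxes = fl, ratios = ratios, co2_proxy_mM = co2,
       limit_cycle = lc)
}
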
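# 13C-enrichment layer: forward/backward flux splitting and the labelled
# mass balances, plus the enrichment-stage simulation.

#' Split net fluxes into forward and backward parts
#'
#' `v_fwd = max(v, 0)`, `v_bwd = max(-v, 0)`; the reconstruction
#' `v_fwd - v_bwd` is bitwise identical to the input. Labelled balances use
#' these splits so every term can be multiplied by the enrichment of its
#' substrate species.
#' @param v_net named numeric flux vector
#' @return list with `fwd` and `bwd` (named, both >= 0)
#' @export
split_reversible <- function(v_net) {
  list(fwd = pmax(v_net, 0), bwd = pmax(-v_net, 0))
}

#' Labelled-fraction right-hand side (reference R implementation)
#'
#' For every carbon-tracked species, the same split fluxes as the total
#' balance, each multiplied by the enrichment (labelled/total, defined as 0
#' for an empty pool) of the species that donates carbon to that term. The
#' aldolase cleavage passes the FBP enrichment to both trioses, and the
#' condensation reactions (trehalose-6-phosphate synthase; reverse aldolase)
#' average their substrates' enrichments, which conserves labelled carbon in
#' glucose-equivalent units. Cofactors and phosphate carry no label. For
#' acetate the balance reads
#' `dACE_L/dt = e(PYR) vPDC - e(ACE) vADH - e(ACE) vsinkACE`.
#'
#' @param state total-concentration state vector
#' @param lstate labelled concentrations (named over [carbon_species()])
#' @param t time (s)
#' @param p a `parameter_set`
#' @param env a [phase_env()]
#' @param label_fraction_feed labelled fraction of feed glucose in [0, 1]
#' @return named derivative vector over the labelled species
#' @export
ode_rhs_labelled <- function(state, lstate, t, p, env, label_fraction_feed = 0) {
  stopifnot(label_fraction_feed >= 0, label_fraction_feed <= 1)
  cs <- carbon_species()
  y <- as.numeric(state[model_species()])
  names(y) <- model_species()
  L <- as.numeric(lstate[cs]); names(L) <- cs
  e <- setNames(numeric(length(cs)), cs)
  pos <- y[cs] > 1e-12
  e[pos] <- L[pos] / y[cs][pos]
  v <- model_fluxes(state, t, p, env)
  s <- split_reversible(v)
  f <- s$fwd; b <- s$bwd
  net <- function(r, sub, prod) f[[r]] * e[[sub]] - b[[r]] * e[[prod]]
  d <- setNames(numeric(length(cs)), cs)
  d["GLCi"] <- net("HXT", "GLCec", "GLCi") + 2 * f[["NTH1"]] * e[["TREc"]] +
    2 * f[["ATH1"]] * e[["TREv"]] - net("HXK", "GLCi", "G6P")
  d["G6P"] <- net("HXK", "GLCi", "G6P") - net("PGI", "G6P", "F6P") -
    net("PGM1", "G6P", "G1P") - f[["TPS1"]] * e[["G6P"]] -
    f[["sink_G6P"]] * e[["G6P"]]
  d["F6P"] <- net("PGI", "G6P", "F6P") - f[["PFK"]] * e[["F6P"]]
  d["FBP"] <- f[["PFK"]] * e[["F6P"]] - f[["FBA"]] * e[["FBP"]] +
    b[["FBA"]] * 0.5 * (e[["DHAP"]] + e[["GAP"]])
  d["DHAP"] <- f[["FBA"]] * e[["FBP"]] - b[["FBA"]] * e[["DHAP"]] -
    net("TPI", "DHAP", "GAP") - f[["G3PDH"]] * e[["DHAP"]]
  d["GAP"] <- f[["FBA"]] * e[["FBP"]] - b[["FBA"]] * e[["GAP"]] +
    net("TPI", "DHAP", "GAP") - net("GAPDH", "GAP", "BPG")
  d["BPG"] <- net("GAPDH", "GAP", "BPG") - net("PGK", "BPG", "P3G")
  d["P3G"] <- net("PGK", "BPG", "P3G") - net("GPM", "P3G", "P2G") -
    f[["sink_P3G"]] * e[["P3G"]]
  d["P2G"] <- net("GPM", "P3G", "P2G") - net("ENO", "P2G", "PEP")
  d["PEP"] <- net("ENO", "P2G", "PEP") - f[["PYK"]] * e[["PEP"]]
  d["PYR"] <- f[["PYK"]] * e[["PEP"]] - f[["PDC"]] * e[["PYR"]] -
    f[["sink_PYR"]] * e[["PYR"]]
  d["ACE"] <- f[["PDC"]] * e[["PYR"]] - f[["ADH"]] * e[["ACE"]] -
    f[["sink_ACE"]] * e[["ACE"]]
  d["G1P"] <- net("PGM1", "G6P", "G1P") - net("UGP", "G1P", "UDPG") +
    f[["GLY_DEG"]] * e[["GLYCOGEN"]]
  d["UDPG"] <- net("UGP", "G1P", "UDPG") - f[["TPS1"]] * e[["UDPG"]] -
    f[["GLY_SYNTH"]] * e[["UDPG"]]
  d["T6P"] <- f[["TPS1"]] * 0.5 * (e[["G6P"]] + e[["UDPG"]]) -
    f[["TPS2"]] * e[["T6P"]]
  d["TREc"] <- f[["TPS2"]] * e[["T6P"]] - f[["NTH1"]] * e[["TREc"]] -
    net("AGT1", "TREc", "TREec") - net("VACT", "TREc", "TREv")
  d["G3P"] <- f[["G3PDH"]] * e[["DHAP"]] - f[["GPP"]] * e[["G3P"]]
  d["GLYCEROL"] <- f[["GPP"]] * e[["G3P"]] - f[["GLYC_EX"]] * e[["GLYCEROL"]]
  d["GLYCOGEN"] <- f[["GLY_SYNTH"]] * e[["UDPG"]] - f[["GLY_DEG"]] * e[["GLYCOGEN"]]
  d["TREv"] <- (net("VACT", "TREc", "TREv") - f[["ATH1"]] * e[["TREv"]]) /
    env$fvac
  din <- env$fin / y[["VOL"]]
  d["GLCec"] <- if (length(env$clamp_t)) 0 else
    din * label_fraction_feed * env$cfeed - din * L[["GLCec"]] -
    env$phi * net("HXT", "GLCec", "GLCi")
  d["TREec"] <- -din * L[["TREec"]] + env$phi * net("AGT1", "TREc", "TREec")
  d
}

#' Simulate the 13C-enrichment stage
#'
#' Starting from the end state of the repetitive-cycle simulation with all
#' pools unlabelled, runs `n_cycles` further cycles in which the feed
#' glucose is labelled at `label_fraction` (99% by default), and returns
#' per-species enrichment (%) on a regular cycle-time grid.
#'
#' @param post_cycle_state `model_state` after the unlabelled cycles
#' @param p a `parameter_set`
#' @param protocol a [feed_protocol()]
#' @param label_fraction labelled fraction of feed glucose
#' @param n_cycles number of labelled cycles (profiles from the last)
#' @param out_dt output resolution (s)
#' @param rtol,atol integrator tolerances
#' @return an `ff_enrichment`: list with `time`, `enrichment` (% matrix over
#'   carbon species), `labelled`, `totals` matrices and the trajectory
#' @export
simulate_enrichment <- function(post_cycle_state, p, protocol = feed_protocol(),
                                label_fraction = protocol$label_fraction,
                                n_cycles = 1, out_dt = 1,
                                rtol = 1e-8, atol = 1e-10) {
  traj <- run_cycles(post_cycle_state, p, protocol, n_cycles = n_cycles,
                     out_dt = out_dt, keep = "last", labelled = TRUE,
                     lfeed = label_fraction, rtol = rtol, atol = atol)
  cs <- carbon_species()
  totals <- traj$states[, cs, drop = FALSE]
  lab <- traj$states[, paste0(cs, "_L"), drop = FALSE]
  colnames(lab) <- cs
  enr <- matrix(0, nrow(totals), ncol(totals), dimnames = dimnames(totals))
  pos <- totals > 1e-12
  enr[pos] <- 100 * lab[pos] / totals[pos]
  structure(list(time = traj$time, enrichment = enr, labelled = lab,
                 totals = totals, trajectory = traj,
                 label_fraction = label_fraction),
            class = "ff_enrichment")
}

#' @export
print.ff_enrichment <- function(x, ...) {
  cat(sprintf("<ff_enrichment: %d species x %d times, feed label %.0f%%>\n",
              ncol(x$enrichment), length(x$time), 100 * x$label_fraction))
  invisible(x)
}

#' Tidy view of enrichment trajectories
#' @param x an `ff_enrichment`
#' @param row.names,optional,... ignored
#' @return data.frame (species, time_s, enrichment_percent)
#' @export
as.data.frame.ff_enrichment <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- do.call(rbind, lapply(colnames(x$enrichment), function(sp)
    data.frame(species = sp, time_s = x$time,
               enrichment_percent = x$enrichment[, sp],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
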
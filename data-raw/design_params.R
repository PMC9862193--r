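# Designs the shipped parameter sets and steady state.
# Strategy: fix a physiologically sensible chemostat steady state (concentrations
# + a flux distribution that closes every internal mass balance exactly), fix the
# printed Table-1 kinetic constants, then solve every remaining Vmax-type constant
# from its rate law at that state. The designed state is then an exact fixed point
# of the chemostat phase, and anchors (residual/max glucose, uptake at 20 s) are
# checked by simulating the feast/famine cycles.
suppressMessages(Rcpp::sourceCpp("src/model.cpp"))

info <- cpp_model_info()
SP <- info$species; RX <- info$reactions; PR <- info$parameters

D <- 0.1 / 3600           # dilution rate (1/s)
phi <- 10.5 * 0.002       # biomass 10.5 gDW/L x 0.002 L/gDW
fvac <- 0.1
MW <- 180.156             # glucose g/mol

# ---- target steady-state concentrations (mM); GLCi/GLCec solved below
conc <- c(GLCi = NA, G6P = 0.8, F6P = 0.15, FBP = 0.15, DHAP = 0.3, GAP = 0.025,
          BPG = 0.015, P3G = 0.9, P2G = 0.12, PEP = 0.7, PYR = 1.2, ACE = 0.3,
          G1P = 0.046, UDPG = 0.49, T6P = 0.01, TREc = 0.025, G3P = 0.15,
          GLYCEROL = 9.45, GLYCOGEN = 55.6, ATP = 2.5, ADP = 1.0, AMP = 0.4,
          NAD = 1.45, NADH = 0.15, PI = 25, TREv = 0.73, GLCec = NA,
          TREec = NA, VOL = 1)

# ---- target flux distribution (mM/s, cytosolic) closing all balances
v_hxt <- 0.265
v_nth1 <- 0.0105; v_ath1 <- 0.0018; v_agt1 <- 2.5e-5; v_vact <- 0.0018
v_tps2 <- v_nth1 + v_agt1 + v_vact           # 0.008
v_tps1 <- v_tps2
v_hxk <- v_hxt + 2 * (v_nth1 + v_ath1)
v_sinkg6p <- 0.03
v_glysyn <- 0.02; v_glydeg <- 0.02
v_ugp <- v_tps1 + v_glysyn - 0              # UDPG consumers
v_pgm1 <- v_ugp - v_glydeg                  # G1P balance
v_pgi <- v_hxk - v_sinkg6p - v_pgm1 - v_tps1
v_pfk <- v_pgi; v_fba <- v_pgi
v_g3pdh <- 0.024
v_tpi <- v_fba - v_g3pdh
v_gapdh <- v_fba + v_tpi
v_pgk <- v_gapdh
v_sinkp3g <- 0.035
v_gpm <- v_pgk - v_sinkp3g; v_eno <- v_gpm; v_pyk <- v_gpm
v_sinkpyr <- 0.35
v_pdc <- v_pyk - v_sinkpyr
v_adh <- 0.005
v_sinkace <- v_pdc - v_adh
v_gpp <- v_g3pdh; v_glycex <- v_gpp
v_mito <- v_gapdh - v_adh - v_g3pdh
v_atpase <- (v_pgk + v_pyk + v_mito) - (v_hxk + v_pfk + v_ugp)
v_pibuf <- (v_gapdh + v_glydeg + v_mito) - (v_gpp + v_tps2 + v_atpase)

target_flux <- c(
  HXT = v_hxt, HXK = v_hxk, PGI = v_pgi, PFK = v_pfk, FBA = v_fba,
  TPI = v_tpi, GAPDH = v_gapdh, PGK = v_pgk, GPM = v_gpm, ENO = v_eno,
  PYK = v_pyk, PDC = v_pdc, ADH = v_adh, G3PDH = v_g3pdh, GPP = v_gpp,
  GLYC_EX = v_glycex, PGM1 = v_pgm1, UGP = v_ugp, TPS1 = v_tps1,
  TPS2 = v_tps2, NTH1 = v_nth1, AGT1 = v_agt1, VACT = v_vact, ATH1 = v_ath1,
  GLY_SYNTH = v_glysyn, GLY_DEG = v_glydeg, ATPase = v_atpase, ADK = 0,
  MITO_NADH = v_mito, PIBUF = v_pibuf, sink_G6P = v_sinkg6p,
  sink_P3G = v_sinkp3g, sink_PYR = v_sinkpyr, sink_ACE = v_sinkace)

# ---- fixed (non-solved) kinetic constants
p <- setNames(rep(NA_real_, length(PR)), PR)
fixed <- c(
  "HXT.Vmax" = 1.70, "HXT.Km" = 0.90, "HXT.Ki" = 0.020, "HXT.Keq" = 1,
  "HXT.GLCec_min" = 0.5, "HXT.sensing" = 1,
  "HXK.Vmax" = 15.75, "HXK.Km_GLC" = 0.11, "HXK.Km_ATP" = 0.15,
  "HXK.Km_G6P" = 30, "HXK.Km_ADP" = 1.0, "HXK.Ki_T6P" = 0.0183,
  "HXK.Keq" = 2000,
  "PGI.Km_G6P" = 8.0, "PGI.Km_F6P" = 2.4, "PGI.Keq" = 0.29,
  "PFK.Km_F6P" = 2.0, "PFK.Km_ATP" = 0.3, "PFK.L0" = 6,
  "PFK.Ki_ATP" = 1.0, "PFK.Ka_AMP" = 1.0, "PFK.Ka_FBP" = 0.05, "PFK.n" = 4,
  "FBA.Km_FBP" = 1.5, "FBA.Km_DHAP" = 3.0, "FBA.Km_GAP" = 0.3,
  "FBA.Keq" = 0.069,
  "TPI.Km_DHAP" = 3.0, "TPI.Km_GAP" = 1.4, "TPI.Keq" = 0.1,
  "GAPDH.Km_GAP" = 0.25, "GAPDH.Km_NAD" = 0.3, "GAPDH.Km_BPG" = 0.15,
  "GAPDH.Km_NADH" = 0.3, "GAPDH.Km_PI" = 5.0, "GAPDH.Keq" = 0.3,
  "PGK.Km_BPG" = 0.15, "PGK.Km_ADP" = 0.5, "PGK.Km_P3G" = 5.0,
  "PGK.Km_ATP" = 1.0, "PGK.Keq" = 3200,
  "GPM.Km_P3G" = 9.0, "GPM.Km_P2G" = 1.2, "GPM.Keq" = 0.19,
  "ENO.Km_P2G" = 1.2, "ENO.Km_PEP" = 7.0, "ENO.Keq" = 6.7,
  "PYK.K05" = 2.0, "PYK.n" = 3, "PYK.Km_ADP" = 0.53, "PYK.Ka_FBP" = 0.5,
  "PDC.K05" = 4.0, "PDC.n" = 2,
  "ADH.Km_ACE" = 2.4, "ADH.Km_NADH" = 0.3,
  "G3PDH.Km_DHAP" = 3.0, "G3PDH.Km_NADH" = 0.3,
  "GPP.Km_G3P" = 1.5,
  "PGM1.Km_G6P" = 8.0, "PGM1.Km_G1P" = 1.2, "PGM1.Keq" = 0.17,
  "UGP.Km_G1P" = 1.2, "UGP.Km_ATP" = 0.5, "UGP.Kia_G1P" = 1.2,
  "UGP.Km_UDPG" = 3.0, "UGP.Km_ADP" = 3.0, "UGP.Keq" = 50,
  "TPS1.Km_G6P" = 2.0, "TPS1.Km_UDPG" = 0.9,
  "TPS2.Km_T6P" = 3.0,
  "NTH1.Km_TRE" = 0.13,
  "AGT1.Km_cyt" = 1.5, "AGT1.Km_ec" = 10, "AGT1.Keq" = 1, "AGT1.Ki_T6P" = 1.0,
  "VACT.Km_cyt" = 1.5, "VACT.Km_vac" = 30, "VACT.Keq" = 30,
  "ATH1.Km_TRE" = 1.2, "ATH1.Ki_T6P" = 1.0,
  "GLY_SYNTH.Ksat_UDPG" = 0.1, "GLY_SYNTH.Ki_GLY" = 60, "GLY_SYNTH.h" = 10,
  "GLY_DEG.Ksat_GLY" = 5,
  "ATPase.Km" = 2.5, "ATPase.n" = 6,
  "ADK.k" = 10, "ADK.Keq" = 1,
  "MITO_NADH.Km_NADH" = 1.2, "MITO_NADH.Km_ADP" = 0.5,
  "PIBUF.k" = 0.05,
  "sink_G6P.Km" = 8, "sink_P3G.Km" = 9, "sink_PYR.Km" = 12,
  "sink_PYR.f" = 0.5, "sink_ACE.Km" = 3)
p[names(fixed)] <- fixed

state_vec <- function(conc) unname(conc[SP])

# glycogen shape tables (scaled below); synthesis peaks after the pulse,
# degradation during famine
syn_shape <- data.frame(t = c(0, 20, 50, 100, 200, 300, 400),
                        v = c(0.4, 1.2, 1.5, 1.0, 0.5, 0.35, 0.4))
deg_shape <- data.frame(t = c(0, 30, 100, 200, 300, 400),
                        v = c(1.0, 0.5, 0.6, 1.1, 1.4, 1.0))
tab_mean <- function(s) {
  area <- sum(0.5 * (head(s$v, -1) + tail(s$v, -1)) * diff(s$t))
  area / diff(range(s$t))
}
sat <- function(S, K) S / (S + K)
cap <- 1 / (1 + (conc["GLYCOGEN"] / fixed["GLY_SYNTH.Ki_GLY"])^fixed["GLY_SYNTH.h"])
syn_scale <- v_glysyn / (sat(conc["UDPG"], fixed["GLY_SYNTH.Ksat_UDPG"]) * cap) / tab_mean(syn_shape)
deg_scale <- v_glydeg / sat(conc["GLYCOGEN"], fixed["GLY_DEG.Ksat_GLY"]) / tab_mean(deg_shape)
syn_tab <- transform(syn_shape, v = v * syn_scale)
deg_tab <- transform(deg_shape, v = v * deg_scale)

mkenv <- function(fin = 0, fout = 0, cfeed = 0, gly_mode = 0) {
  list(phi = phi, fvac = fvac, fin = fin, fout = fout, cfeed = cfeed,
       lfeed = 0, gly_mode = as.integer(gly_mode),
       gly_syn_t = syn_tab$t, gly_syn_v = syn_tab$v,
       gly_deg_t = deg_tab$t, gly_deg_v = deg_tab$v,
       cycle_len = 400, cycle_t0 = 0, clamp_t = numeric(0), clamp_v = numeric(0))
}

flux_at <- function(pvec, conc) {
  pv <- pvec; pv[is.na(pv)] <- 1  # unsolved Vmax placeholder
  cpp_fluxes(state_vec(conc), 0, pv, mkenv())
}

# ---- solve GLCi from HXK (Table-1 constants fixed)
f_glci <- function(x) { cc <- conc; cc["GLCi"] <- x; cc["GLCec"] <- 1
  flux_at(p, cc)[["HXK"]] - v_hxk }
conc["GLCi"] <- uniroot(f_glci, c(1e-4, 5), tol = 1e-14)$root

# ---- solve GLCec from HXT
f_glcec <- function(x) { cc <- conc; cc["GLCec"] <- x
  flux_at(p, cc)[["HXT"]] - v_hxt }
conc["GLCec"] <- uniroot(f_glcec, c(p[["HXT.GLCec_min"]] + 1e-6, 50), tol = 1e-14)$root

# ---- extracellular trehalose from AGT1 secretion balance
conc["TREec"] <- phi * v_agt1 / D

# ---- solve Vmax-like constants linearly (flux proportional to Vmax/k)
vmax_key <- c(PGI = "PGI.Vmax", PFK = "PFK.Vmax", FBA = "FBA.Vmax",
  TPI = "TPI.Vmax", GAPDH = "GAPDH.Vmax", PGK = "PGK.Vmax", GPM = "GPM.Vmax",
  ENO = "ENO.Vmax", PYK = "PYK.Vmax", PDC = "PDC.Vmax", ADH = "ADH.Vmax",
  G3PDH = "G3PDH.Vmax", GPP = "GPP.Vmax", "GLYC_EX" = "GLYC_EX.k",
  PGM1 = "PGM1.Vmax", UGP = "UGP.Vmax", TPS1 = "TPS1.Vmax",
  TPS2 = "TPS2.Vmax", NTH1 = "NTH1.Vmax", AGT1 = "AGT1.Vmax",
  VACT = "VACT.Vmax", ATH1 = "ATH1.Vmax", ATPase = "ATPase.k",
  "MITO_NADH" = "MITO_NADH.Vmax", sink_G6P = "sink_G6P.Vmax",
  sink_P3G = "sink_P3G.Vmax", sink_PYR = "sink_PYR.Vmax",
  sink_ACE = "sink_ACE.Vmax")
vunit <- flux_at(p, conc)
for (rx in names(vmax_key)) p[[vmax_key[[rx]]]] <- target_flux[[rx]] / vunit[[rx]]

# ---- phosphate buffer reference
p[["PIBUF.Pi_ref"]] <- conc[["PI"]] + v_pibuf / p[["PIBUF.k"]]

stopifnot(!anyNA(p), all(p[unname(vmax_key)] > 0))

# ---- verify the designed state is a fixed point of the chemostat phase
cs_mM <- conc[["GLCec"]] + phi * v_hxt / D
fin_ss <- D * conc[["VOL"]]
env_ss <- mkenv(fin = fin_ss, fout = fin_ss, cfeed = cs_mM)
dy <- cpp_rhs(state_vec(conc), 0, unname(p), env_ss)
cat("max |dy/dt| at designed SS:", max(abs(dy)), "\n")
cat("GLCec_ss:", conc[["GLCec"]], "mM =", conc[["GLCec"]] * MW / 1000, "g/L\n")
cat("GLCi_ss:", conc[["GLCi"]], "  Cs_chem:", cs_mM * MW / 1000, "g/L\n")

# ---- simulate 20 feast/famine cycles and report the calibration anchors
simulate_cycles <- function(pvec, y0, n_cycles = 20, dt_out = 2) {
  y <- y0; t0 <- 0
  fin <- D * y0[[29]]; cfeed <- 20 * cs_mM
  dvol <- fin * 20; fout2 <- dvol / 240
  traj <- NULL
  for (cyc in seq_len(n_cycles)) {
    seg <- function(times, env) {
      r <- cpp_integrate(y, times, unname(pvec), env, 1e-8, 1e-10)
      if (!r$ok) { saveRDS(list(y=r$ylast, p=pvec, env=env, msg=r$message), "scratch/fail.rds"); stop(sprintf("cycle %d t %g: %s", cyc, times[1], r$message)) }
      y <<- r$y[nrow(r$y), ]
      if (cyc == n_cycles) traj <<- rbind(traj, cbind(times, r$y))
      invisible(NULL)
    }
    seg(t0 + seq(0, 20, by = 1), { e <- mkenv(fin = fin, fout = 0, cfeed = cfeed, gly_mode = 1); e$cycle_t0 <- t0; e })
    seg(t0 + seq(20, 260, by = dt_out), { e <- mkenv(fin = 0, fout = fout2, cfeed = 0, gly_mode = 1); e$cycle_t0 <- t0; e })
    seg(t0 + seq(260, 400, by = dt_out), { e <- mkenv(0, 0, 0, gly_mode = 1); e$cycle_t0 <- t0; e })
    t0 <- t0 + 400
  }
  list(y_end = y, traj = traj)
}

t0 <- Sys.time()
sim <- simulate_cycles(p, state_vec(conc))
cat("20 cycles in", round(as.numeric(Sys.time() - t0, units = "secs"), 2), "s\n")

tr <- sim$traj; tt <- tr[, 1] - min(tr[, 1])
colnames(tr) <- c("t", SP)
env_cyc <- mkenv(gly_mode = 1); env_cyc$cycle_t0 <- min(tr[, 1])
fl <- t(apply(tr, 1, function(row) cpp_fluxes(row[-1], row[[1]], unname(p), env_cyc)))
glc_g <- tr[, "GLCec"] * MW / 1000
cat("\n--- final-cycle anchors ---\n")
cat("GLCec max:", max(glc_g), "g/L at t=", tt[which.max(glc_g)], "; min:", min(glc_g), "g/L\n")
cat("HXT uptake at 20 s:", fl[which.min(abs(tt - 20)), "HXT"], "mM/s; at 400 s:",
    fl[nrow(fl), "HXT"], "mM/s\n")
cat("max TPS1:", max(fl[, "TPS1"]), " max HXK:", max(fl[, "HXK"]),
    " ratio %:", 100 * max(fl[, "TPS1"]) / max(fl[, "HXK"]), "\n")
imax <- function(s) tt[which.max(tr[, s])]
cat("peak times: G6P", imax("G6P"), "FBP", imax("FBP"), "BPG", imax("BPG"),
    "P3G", imax("P3G"), "PEP", imax("PEP"), "T6P", imax("T6P"), "\n")
cat("ATP range:", range(tr[, "ATP"]), " sum adenylates drift:",
    max(abs(rowSums(tr[, c("ATP", "ADP", "AMP")]) - sum(conc[c("ATP", "ADP", "AMP")]))), "\n")
cat("end-state vs designed SS (rel):",
    max(abs(sim$y_end - state_vec(conc)) / pmax(abs(state_vec(conc)), 1e-6)), "\n")

# stash results for inspection
saveRDS(list(p = p, conc = conc, cs_mM = cs_mM, syn_tab = syn_tab,
             deg_tab = deg_tab, tr = tr, fl = fl), "scratch/design_result.rds")

# ---- reference (pre-adaptation) parameter set: Table-1 reference values for
# HXT and HXK/GLK, original NTH1 affinity, higher maintenance ATPase
p_ref <- p
p_ref[["HXT.Vmax"]] <- 8.13;  p_ref[["HXT.Km"]] <- 1.01
p_ref[["HXK.Vmax"]] <- 6.25;  p_ref[["HXK.Km_GLC"]] <- 0.35
p_ref[["HXK.Ki_T6P"]] <- 0.0073
p_ref[["NTH1.Km_TRE"]] <- 2.11
p_ref[["ATPase.k"]] <- p[["ATPase.k"]] * 1.4

cat("\n--- reference-set chemostat (Newton polish) ---\n")
newton_ss <- function(pvec, y0) {
  iAMP <- which(SP=="AMP"); iNADH <- which(SP=="NADH"); iVOL <- which(SP=="VOL")
  iATP <- which(SP=="ATP"); iADP <- which(SP=="ADP"); iNAD <- which(SP=="NAD")
  Atot <- sum(y0[c(iATP,iADP,iAMP)]); Ntot <- y0[iNAD]+y0[iNADH]
  free <- setdiff(seq_along(SP), c(iAMP,iNADH,iVOL))
  expand <- function(x) { y <- numeric(length(SP)); y[free] <- x
    y[iAMP] <- Atot - y[iATP] - y[iADP]; y[iNADH] <- Ntot - y[iNAD]; y[iVOL] <- y0[iVOL]; y }
  fres <- function(x) cpp_rhs(expand(x), 0, unname(pvec), env_ss)[free]
  x <- y0[free]
  for (it in 1:50) {
    f0 <- fres(x)
    if (max(abs(f0)) < 1e-12) break
    J <- matrix(0, length(x), length(x))
    for (j in seq_along(x)) { dx <- 1e-7*max(abs(x[j]),1e-4); xp <- x; xp[j] <- xp[j]+dx
      J[,j] <- (fres(xp)-f0)/dx }
    x <- x + solve(J, -f0)
  }
  expand(x)
}
y_ref <- newton_ss(p_ref, state_vec(conc))
dy_ref <- cpp_rhs(y_ref, 0, unname(p_ref), env_ss)
cat("residual:", max(abs(dy_ref)), " min conc:", min(y_ref), "\n")
names(y_ref) <- SP
print(round(y_ref[c("GLCec","GLCi","G6P","T6P","ATP","TREc","GLYCOGEN")], 4))
stopifnot(max(abs(dy_ref)) < 1e-10, all(y_ref > 0))

# ---- write shipped artifacts
unit_of <- function(key) {
  suf <- sub("^[^.]+\\.", "", key)
  if (suf %in% c("Vmax")) return("mM/s")
  if (grepl("^(Km|Ki|Ka|K05|Kia|Ksat)", suf)) return("mM")
  if (suf %in% c("GLCec_min", "Pi_ref", "Ki_GLY", "Ki_T6P")) return("mM")
  if (suf %in% c("Keq", "n", "h", "f", "L0", "sensing")) return("1")
  if (suf == "k") return("1/s")
  "1"
}
write_pset <- function(pvec, role, path) {
  units <- vapply(names(pvec), unit_of, "")
  units[["ADK.k"]] <- "1/(mM.s)"
  units[["ATPase.k"]] <- "mM/s"  # Hill Vmax
  obj <- list(role = role,
              description = paste("Kinetic constants for the yeast",
                                  "glycolysis/trehalose-cycle feast-famine model"),
              values = as.list(pvec), units = as.list(units))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_pset(p, "estimated", "inst/extdata/params_calibrated.json")
write_pset(p_ref, "reference", "inst/extdata/params_reference.json")
jsonlite::write_json(as.list(conc[SP]), "inst/extdata/steady_state_calibrated.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
write.csv(data.frame(time_s = syn_tab$t, flux_mM_per_s = syn_tab$v),
          "inst/extdata/glycogen_synthesis.csv", row.names = FALSE)
write.csv(data.frame(time_s = deg_tab$t, flux_mM_per_s = deg_tab$v),
          "inst/extdata/glycogen_degradation.csv", row.names = FALSE)
proto <- list(dilution_rate = 0.1, cs_chem_gL = cs_mM * MW / 1000,
              biomass_gdw_L = 10.5, biomass_volume_fraction = 0.002,
              vacuole_fraction = 0.1, cycle_length = 400, feed_window = 20,
              feed_multiplier = 20, outflow_end = 260, n_cycles = 20,
              residence_pre = 5, broth_volume_L = 1,
              label_fraction = 0.99)
jsonlite::write_json(proto, "inst/extdata/protocol_default.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("artifacts written; cs_chem =", proto$cs_chem_gL, "g/L\n")
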
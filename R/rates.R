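# Kinetic rate laws (reference R implementation). The compiled right-hand
# side in src/ is the fast path used by the integrator; the functions here are
# the auditable definition of every law and are asserted against the compiled
# fluxes to near machine precision by the test suite.

#' Facilitated-diffusion hexose transport with glucose-sensing threshold
#'
#' Carrier kinetics with symmetric Km and trans-inhibition:
#' \deqn{v = (V_m/K_m)\,(G_{ec}' - G_i/K_{eq}) / (1 + G_{ec}'/K_m + G_i/K_m +
#'       G_{ec}' G_i / (K_i K_m^2))}
#' where \eqn{G_{ec}' = \max(G_{ec} - G_{ec,min}, 0)} when sensing is on and
#' \eqn{G_{ec}' = G_{ec}} otherwise. With `Keq = 1` the law is antisymmetric
#' in its two substrates (sensing off), i.e. net rate vanishes at zero
#' trans-membrane gradient.
#'
#' @param glc_ec extracellular glucose (mM)
#' @param glc_i intracellular glucose (mM)
#' @param p a `parameter_set` (uses the `HXT.*` constants)
#' @param sensing override the `HXT.sensing` flag (logical), or `NULL` to use
#'   the flag from `p`
#' @return net uptake rate (mM/s, cytosolic basis)
#' @export
rate_hxt <- function(glc_ec, glc_i, p, sensing = NULL) {
  if (any(glc_ec < 0) || any(glc_i < 0)) stop("negative concentration")
  on <- if (is.null(sensing)) p[["HXT.sensing"]] > 0.5 else isTRUE(sensing)
  Km <- p[["HXT.Km"]]
  xec <- if (on) pmax(glc_ec - p[["HXT.GLCec_min"]], 0) else glc_ec
  (p[["HXT.Vmax"]] / Km) * (xec - glc_i / p[["HXT.Keq"]]) /
    (1 + xec / Km + glc_i / Km + xec * glc_i / (p[["HXT.Ki"]] * Km^2))
}

#' Reversible uni-uni Michaelis-Menten, optional competitive inhibition
#'
#' \deqn{v = \mathrm{inh}\; (V_m/K_s)(S - P/K_{eq}) / (1 + S/K_s + P/K_p)}
#' with `inh = 1/(1 + I/Ki)` when an inhibitor is configured. Used for AGT1
#' (T6P-inhibited), the vacuolar trehalose transporter, PGI, TPI, GPM, ENO,
#' PGM1.
#'
#' @param s,prod substrate and product concentrations (mM)
#' @param Vmax,Km_s,Km_p,Keq kinetic constants
#' @param inhibitor,Ki optional inhibitor concentration and constant
#' @return net rate (mM/s), sign follows the thermodynamic gradient
#' @export
rate_mm_rev <- function(s, prod, Vmax, Km_s, Km_p, Keq,
                        inhibitor = 0, Ki = Inf) {
  if (any(s < 0) || any(prod < 0)) stop("negative concentration")
  inh <- 1 / (1 + inhibitor / Ki)
  inh * (Vmax / Km_s) * (s - prod / Keq) / (1 + s / Km_s + prod / Km_p)
}

#' Irreversible Michaelis-Menten, optional inhibition factor
#'
#' \deqn{v = V_m S/(K_m+S) \cdot 1/(1+I/K_i) \ge 0.} Used for the trehalases
#' (NTH1, T6P-inhibited ATH1) and the sink reactions.
#' @param s substrate (mM)
#' @param Vmax,Km constants
#' @param inhibitor,Ki optional inhibition
#' @export
rate_mm_irrev <- function(s, Vmax, Km, inhibitor = 0, Ki = Inf) {
  if (any(s < 0)) stop("negative concentration")
  Vmax * s / (Km + s) / (1 + inhibitor / Ki)
}

#' Ordered bi-bi rate law (UDP-glucose pyrophosphorylase)
#'
#' Cleland ordered bi-bi with the leading-substrate inhibition constant
#' `Kia` and lumped product terms; UTP/UDP are proxied by ATP/ADP:
#' \deqn{v = V_m (AB - PQ/K_{eq}) / (K_{ia}K_B(1 + P/K_P + Q/K_Q + PQ/K_PK_Q)
#'       + K_B A + K_A B + AB)}
#' @param g1p,utp_proxy substrates A, B (mM)
#' @param udpg,udp_proxy products P, Q (mM)
#' @param p a `parameter_set` (uses `UGP.*`)
#' @export
rate_ugp <- function(g1p, utp_proxy, udpg, udp_proxy, p) {
  if (any(c(g1p, utp_proxy, udpg, udp_proxy) < 0)) stop("negative concentration")
  A <- g1p; B <- utp_proxy; P <- udpg; Q <- udp_proxy
  Ka <- p[["UGP.Km_G1P"]]; Kb <- p[["UGP.Km_ATP"]]; Kia <- p[["UGP.Kia_G1P"]]
  Kp <- p[["UGP.Km_UDPG"]]; Kq <- p[["UGP.Km_ADP"]]
  den <- Kia * Kb * (1 + P / Kp + Q / Kq + P * Q / (Kp * Kq)) +
    Kb * A + Ka * B + A * B
  p[["UGP.Vmax"]] * (A * B - P * Q / p[["UGP.Keq"]]) / den
}

#' Phenomenological glycogen flux: interpolated base rate with saturation
#'
#' The base flux is a piecewise-linear interpolation over cycle time
#' (periodic extension across cycles), scaled by a substrate saturation
#' factor \eqn{S/(S+K_{sat})}. Synthesis additionally carries a
#' glycogen-capacity factor \eqn{1/(1+(G/K_i)^h)} so that the glycogen pool
#' has a stable operating point.
#'
#' @param t time (s); interpreted modulo `cycle_len` when `periodic`
#' @param s saturating substrate (UDPG for synthesis, glycogen for
#'   degradation), mM
#' @param table data.frame with columns `time_s`, `flux_mM_per_s`
#' @param Ksat saturation constant (mM)
#' @param glycogen,Ki_gly,h optional capacity inhibition (synthesis)
#' @param cycle_len cycle length (s)
#' @param periodic allow times outside the table range (periodic extension)
#' @export
rate_glycogen <- function(t, s, table, Ksat, glycogen = NULL, Ki_gly = NULL,
                          h = NULL, cycle_len = 400, periodic = TRUE) {
  if (any(s < 0)) stop("negative concentration")
  tc <- if (periodic) t %% cycle_len else t
  if (!periodic && (any(tc < min(table$time_s)) || any(tc > max(table$time_s))))
    stop("time outside interpolation table (periodic extension disabled)")
  base <- approx(table$time_s, table$flux_mM_per_s, xout = tc, rule = 2)$y
  v <- base * s / (s + Ksat)
  if (!is.null(glycogen)) v <- v / (1 + (glycogen / Ki_gly)^h)
  v
}

#' Two-state (MWC) allosteric phosphofructokinase
#'
#' Tense/relaxed-state rational law: with \eqn{a = F6P/K_m},
#' \deqn{v = V_m \frac{ATP}{K_{m,ATP}+ATP} \frac{a(1+a)^{n-1}}{(1+a)^n + L}}
#' where the allosteric ratio
#' \eqn{L = L_0 [(1+ATP/K_{i,ATP}) / ((1+AMP/K_{a,AMP})(1+FBP/K_{a,FBP}))]^n}
#' is raised by ATP and lowered by AMP and FBP.
#' @param f6p,atp,amp,fbp effector concentrations (mM)
#' @param p a `parameter_set` (uses `PFK.*`)
#' @export
rate_pfk <- function(f6p, atp, amp, fbp, p) {
  if (any(c(f6p, atp, amp, fbp) < 0)) stop("negative concentration")
  a <- f6p / p[["PFK.Km_F6P"]]
  n <- p[["PFK.n"]]
  L <- p[["PFK.L0"]] * ((1 + atp / p[["PFK.Ki_ATP"]]) /
    ((1 + amp / p[["PFK.Ka_AMP"]]) * (1 + fbp / p[["PFK.Ka_FBP"]])))^n
  on <- (1 + a)^(n - 1)
  p[["PFK.Vmax"]] * atp / (p[["PFK.Km_ATP"]] + atp) * a * on /
    (on * (1 + a) + L)
}

#' Hill-type pyruvate kinase with FBP feed-forward activation
#'
#' \deqn{v = V_m \frac{PEP^n}{K^n + PEP^n}\frac{ADP}{K_{m,ADP}+ADP}}, with
#' the half-saturation lowered by FBP: \eqn{K = K_{0.5}/(1 + FBP/K_a)}. The
#' rate is strictly increasing in FBP at fixed substrates; `n = 1` reduces to
#' Michaelis-Menten.
#' @param pep,adp,fbp concentrations (mM)
#' @param p a `parameter_set` (uses `PYK.*`)
#' @export
rate_pyk <- function(pep, adp, fbp, p) {
  if (any(c(pep, adp, fbp) < 0)) stop("negative concentration")
  K <- p[["PYK.K05"]] / (1 + fbp / p[["PYK.Ka_FBP"]])
  s <- pep^p[["PYK.n"]]
  p[["PYK.Vmax"]] * s / (K^p[["PYK.n"]] + s) * adp / (p[["PYK.Km_ADP"]] + adp)
}

#' Hill-type pyruvate decarboxylase
#' @param pyr pyruvate (mM)
#' @param p a `parameter_set` (uses `PDC.*`)
#' @export
rate_pdc <- function(pyr, p) {
  if (any(pyr < 0)) stop("negative concentration")
  s <- pyr^p[["PDC.n"]]
  p[["PDC.Vmax"]] * s / (p[["PDC.K05"]]^p[["PDC.n"]] + s)
}

.mm_rev_bibi <- function(Vm, A, B, P, Q, Ka, Kb, Kp, Kq, Keq, extra = 0) {
  Vm / (Ka * Kb) * (A * B - P * Q / Keq) /
    ((1 + A / Ka + P / Kp + extra) * (1 + B / Kb + Q / Kq))
}

#' Full flux vector at a state (reference R implementation)
#'
#' Evaluates every reaction rate at the given state, mirroring the compiled
#' fast path reaction by reaction. Concentrations are clamped at zero, as in
#' the compiled code.
#' @param state named numeric state vector over [model_species()]
#' @param t time (s), used by the glycogen interpolation
#' @param p a `parameter_set`
#' @param env phase environment from [phase_env()]
#' @return named numeric vector over [model_reactions()]
#' @export
model_fluxes <- function(state, t, p, env) {
  y <- pmax(as.numeric(state[model_species()]), 0)
  names(y) <- model_species()
  g <- function(s) y[[s]]
  glcec <- if (length(env$clamp_t))
    approx(env$clamp_t, env$clamp_v, xout = (t - env$cycle_t0) %% env$cycle_len,
           rule = 2)$y else g("GLCec")
  v <- setNames(numeric(length(model_reactions())), model_reactions())
  v["HXT"] <- {
    Km <- p[["HXT.Km"]]
    xec <- if (p[["HXT.sensing"]] > 0.5) max(glcec - p[["HXT.GLCec_min"]], 0) else glcec
    (p[["HXT.Vmax"]] / Km) * (xec - g("GLCi") / p[["HXT.Keq"]]) /
      (1 + xec / Km + g("GLCi") / Km + xec * g("GLCi") / (p[["HXT.Ki"]] * Km^2))
  }
  v["HXK"] <- .mm_rev_bibi(p[["HXK.Vmax"]], g("GLCi"), g("ATP"), g("G6P"), g("ADP"),
                           p[["HXK.Km_GLC"]], p[["HXK.Km_ATP"]], p[["HXK.Km_G6P"]],
                           p[["HXK.Km_ADP"]], p[["HXK.Keq"]],
                           extra = g("T6P") / p[["HXK.Ki_T6P"]])
  v["PGI"] <- rate_mm_rev(g("G6P"), g("F6P"), p[["PGI.Vmax"]], p[["PGI.Km_G6P"]],
                          p[["PGI.Km_F6P"]], p[["PGI.Keq"]])
  v["PFK"] <- rate_pfk(g("F6P"), g("ATP"), g("AMP"), g("FBP"), p)
  v["FBA"] <- {
    Kf <- p[["FBA.Km_FBP"]]; Kd <- p[["FBA.Km_DHAP"]]; Kg <- p[["FBA.Km_GAP"]]
    (p[["FBA.Vmax"]] / Kf) * (g("FBP") - g("DHAP") * g("GAP") / p[["FBA.Keq"]]) /
      (1 + g("FBP") / Kf + g("DHAP") / Kd + g("GAP") / Kg +
         g("DHAP") * g("GAP") / (Kd * Kg))
  }
  v["TPI"] <- rate_mm_rev(g("DHAP"), g("GAP"), p[["TPI.Vmax"]], p[["TPI.Km_DHAP"]],
                          p[["TPI.Km_GAP"]], p[["TPI.Keq"]])
  v["GAPDH"] <- .mm_rev_bibi(p[["GAPDH.Vmax"]], g("GAP"), g("NAD"), g("BPG"), g("NADH"),
                             p[["GAPDH.Km_GAP"]], p[["GAPDH.Km_NAD"]],
                             p[["GAPDH.Km_BPG"]], p[["GAPDH.Km_NADH"]],
                             p[["GAPDH.Keq"]]) *
    g("PI") / (p[["GAPDH.Km_PI"]] + g("PI"))
  v["PGK"] <- .mm_rev_bibi(p[["PGK.Vmax"]], g("BPG"), g("ADP"), g("P3G"), g("ATP"),
                           p[["PGK.Km_BPG"]], p[["PGK.Km_ADP"]], p[["PGK.Km_P3G"]],
                           p[["PGK.Km_ATP"]], p[["PGK.Keq"]])
  v["GPM"] <- rate_mm_rev(g("P3G"), g("P2G"), p[["GPM.Vmax"]], p[["GPM.Km_P3G"]],
                          p[["GPM.Km_P2G"]], p[["GPM.Keq"]])
  v["ENO"] <- rate_mm_rev(g("P2G"), g("PEP"), p[["ENO.Vmax"]], p[["ENO.Km_P2G"]],
                          p[["ENO.Km_PEP"]], p[["ENO.Keq"]])
  v["PYK"] <- rate_pyk(g("PEP"), g("ADP"), g("FBP"), p)
  v["PDC"] <- rate_pdc(g("PYR"), p)
  v["ADH"] <- p[["ADH.Vmax"]] * g("ACE") / (p[["ADH.Km_ACE"]] + g("ACE")) *
    g("NADH") / (p[["ADH.Km_NADH"]] + g("NADH"))
  v["G3PDH"] <- p[["G3PDH.Vmax"]] * g("DHAP") / (p[["G3PDH.Km_DHAP"]] + g("DHAP")) *
    g("NADH") / (p[["G3PDH.Km_NADH"]] + g("NADH"))
  v["GPP"] <- rate_mm_irrev(g("G3P"), p[["GPP.Vmax"]], p[["GPP.Km_G3P"]])
  v["GLYC_EX"] <- p[["GLYC_EX.k"]] * g("GLYCEROL")
  v["PGM1"] <- rate_mm_rev(g("G6P"), g("G1P"), p[["PGM1.Vmax"]], p[["PGM1.Km_G6P"]],
                           p[["PGM1.Km_G1P"]], p[["PGM1.Keq"]])
  v["UGP"] <- rate_ugp(g("G1P"), g("ATP"), g("UDPG"), g("ADP"), p)
  v["TPS1"] <- p[["TPS1.Vmax"]] * g("G6P") / (p[["TPS1.Km_G6P"]] + g("G6P")) *
    g("UDPG") / (p[["TPS1.Km_UDPG"]] + g("UDPG"))
  v["TPS2"] <- rate_mm_irrev(g("T6P"), p[["TPS2.Vmax"]], p[["TPS2.Km_T6P"]])
  v["NTH1"] <- rate_mm_irrev(g("TREc"), p[["NTH1.Vmax"]], p[["NTH1.Km_TRE"]])
  v["AGT1"] <- rate_mm_rev(g("TREc"), g("TREec"), p[["AGT1.Vmax"]], p[["AGT1.Km_cyt"]],
                           p[["AGT1.Km_ec"]], p[["AGT1.Keq"]],
                           inhibitor = g("T6P"), Ki = p[["AGT1.Ki_T6P"]])
  v["VACT"] <- rate_mm_rev(g("TREc"), g("TREv"), p[["VACT.Vmax"]], p[["VACT.Km_cyt"]],
                           p[["VACT.Km_vac"]], p[["VACT.Keq"]])
  v["ATH1"] <- rate_mm_irrev(g("TREv"), p[["ATH1.Vmax"]], p[["ATH1.Km_TRE"]],
                             inhibitor = g("T6P"), Ki = p[["ATH1.Ki_T6P"]])
  tab_mean <- function(tt, vv) {
    area <- sum(0.5 * (head(vv, -1) + tail(vv, -1)) * diff(tt))
    area / (max(tt) - min(tt))
  }
  tc <- (t - env$cycle_t0) %% env$cycle_len
  syn_base <- if (env$gly_mode == 1)
    approx(env$gly_syn_t, env$gly_syn_v, xout = tc, rule = 2)$y
  else tab_mean(env$gly_syn_t, env$gly_syn_v)
  deg_base <- if (env$gly_mode == 1)
    approx(env$gly_deg_t, env$gly_deg_v, xout = tc, rule = 2)$y
  else tab_mean(env$gly_deg_t, env$gly_deg_v)
  v["GLY_SYNTH"] <- syn_base * g("UDPG") / (g("UDPG") + p[["GLY_SYNTH.Ksat_UDPG"]]) /
    (1 + (g("GLYCOGEN") / p[["GLY_SYNTH.Ki_GLY"]])^p[["GLY_SYNTH.h"]])
  v["GLY_DEG"] <- deg_base * g("GLYCOGEN") / (g("GLYCOGEN") + p[["GLY_DEG.Ksat_GLY"]])
  v["ATPase"] <- {
    an <- g("ATP")^p[["ATPase.n"]]
    p[["ATPase.k"]] * an / (p[["ATPase.Km"]]^p[["ATPase.n"]] + an)
  }
  v["ADK"] <- p[["ADK.k"]] * (g("ATP") * g("AMP") - g("ADP")^2 / p[["ADK.Keq"]])
  v["MITO_NADH"] <- p[["MITO_NADH.Vmax"]] *
    g("NADH") / (p[["MITO_NADH.Km_NADH"]] + g("NADH")) *
    g("ADP") / (p[["MITO_NADH.Km_ADP"]] + g("ADP"))
  v["PIBUF"] <- p[["PIBUF.k"]] * (p[["PIBUF.Pi_ref"]] - g("PI"))
  v["sink_G6P"] <- rate_mm_irrev(g("G6P"), p[["sink_G6P.Vmax"]], p[["sink_G6P.Km"]])
  v["sink_P3G"] <- rate_mm_irrev(g("P3G"), p[["sink_P3G.Vmax"]], p[["sink_P3G.Km"]])
  v["sink_PYR"] <- p[["sink_PYR.f"]] *
    rate_mm_irrev(g("PYR"), p[["sink_PYR.Vmax"]], p[["sink_PYR.Km"]])
  v["sink_ACE"] <- rate_mm_irrev(g("ACE"), p[["sink_ACE.Vmax"]], p[["sink_ACE.Km"]])
  v
}

#' Total-concentration right-hand side (reference R implementation)
#'
#' Assembles stoichiometry x flux for the cytosolic species, then adds the
#' compartment and broth terms: vacuolar transfer scaled by the vacuole
#' volume fraction, feed/dilution of the extracellular species scaled by the
#' biomass volume fraction `phi`, and the broth-volume balance. The acetate
#' balance is, explicitly, `dACE/dt = vPDC - vADH - vsinkACE`.
#' @inheritParams model_fluxes
#' @return named derivative vector (same order as the state)
#' @export
ode_rhs_total <- function(state, t, p, env) {
  v <- model_fluxes(state, t, p, env)
  S <- stoichiometry_matrix()
  dy <- as.numeric(S %*% v)
  names(dy) <- rownames(S)
  if (any(!is.finite(v))) {
    bad <- names(v)[!is.finite(v)]
    stop("non-finite rate in reaction ", paste(bad, collapse = ", "))
  }
  din <- env$fin / state[["VOL"]]
  # vacuole: concentration change on vacuolar volume
  dy["TREv"] <- (v[["VACT"]] - v[["ATH1"]]) / env$fvac
  # extracellular balances on broth volume
  dy["GLCec"] <- if (length(env$clamp_t)) 0 else
    din * (env$cfeed - state[["GLCec"]]) - env$phi * v[["HXT"]]
  dy["TREec"] <- -din * state[["TREec"]] + env$phi * v[["AGT1"]]
  dy["VOL"] <- env$fin - env$fout
  dy
}
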
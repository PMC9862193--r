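---
title: "Methods: the feast/famine kinetic model and its estimation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the feast/famine kinetic model and its estimation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
the numerical choices, and the design decisions taken where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The model

### Network and compartments

The state holds 29 variables: cytosolic glycolysis (GLCi, G6P, F6P, FBP,
DHAP, GAP, BPG, P3G, P2G, PEP, PYR, ACE), the glycerol branch (G3P,
GLYCEROL), the storage branch (G1P, UDPG, T6P, cytosolic trehalose TREc,
glycogen in glucose-equivalents), cofactors (ATP, ADP, AMP, NAD, NADH,
Pi), vacuolar trehalose (TREv, on vacuolar volume, a fixed 10% of
cytosolic volume by default), extracellular glucose and trehalose (broth
volume), and the broth volume itself. Intracellular balances are mM on
cytosolic volume; the biomass volume fraction (0.002 L gDW⁻¹ × biomass
concentration) converts fluxes to broth basis. Biomass is held constant
within cycles — at the 400-s timescale enzyme and biomass changes are
negligible.

Thirty-four reactions connect them (see `model_reactions()` and
`stoichiometry_matrix()`). Three deserve comment because they are not in
the textbook network:

* **PIBUF**, a first-order phosphate exchange towards a reference
  concentration, standing in for vacuolar polyphosphate buffering. The
  proxy treatment of UTP/UDP (see below) and the lumped sinks leave the
  phosphate balance structurally open; the buffer closes it. Its rate
  constant (0.05 s⁻¹) makes Pi a fast pool; the reference value is solved
  at design time so the buffer carries the residual Pi flux at steady
  state.
* **GLYC_EX**, first-order glycerol excretion, which gives the glycerol
  pool a steady state.
* The **glycogen capacity factor** `1/(1+(GLY/Ki)^h)` on synthesis
  (default Ki = 60 mM, h = 10). Without it the phenomenological glycogen
  fluxes have no stable operating point: the interpolated base fluxes are
  constants, so any parameter change that shifts the UDPG saturation
  produces unbounded glycogen drift. The steep factor both stabilizes the
  pool and makes its relaxation time (~500 s) short enough that 20 cycles
  reach a limit cycle.

### Rate-law families

Most reactions are reversible Michaelis–Menten (uni-uni or convenience
bi-bi, thermodynamically consistent: the net rate vanishes exactly at
`Γ = Keq`). Exceptions:

* **HXT**: facilitated diffusion with symmetric Km, trans-inhibition
  constant Ki, equilibrium constant 1, and the glucose-sensing threshold
  `G'ec = max(Gec − Gec,min, 0)` implemented as a continuous
  piecewise-linear clamp (integrator-friendly; only the active branch of
  the threshold law is ever stated in the source formulation).
* **PFK**: a compact two-state (MWC) law; ATP raises and AMP/FBP lower
  the tense/relaxed ratio `L`. The baseline allosteric state matters: the
  shipped L₀ = 6 with effector constants (Ki,ATP = 1 mM, Ka,AMP = 1 mM,
  Ka,FBP = 0.05 mM) puts the enzyme in a moderate T-state at the
  chemostat, lets the FBP surge switch it on during the feast
  (autocatalytic activation), and switches it off during famine. A
  hair-trigger baseline (large L₀) destabilizes the whole network — the
  classic "turbo glycolysis" failure, see §4.
* **PYK/PDC**: Hill laws; FBP lowers PYK's half-saturation (feed-forward
  activation). With Hill coefficient 1 both reduce exactly to MM.
* **UGP**: ordered bi-bi (G1P leading) with UTP/UDP proxied by ATP/ADP.
  The proxy is deliberate: nucleotide interconversion is not modelled, so
  UGP charges the adenylate pool one ATP per UDPG, and the UDP released
  by TPS1 and glycogen synthase is dropped — this keeps ATP+ADP+AMP
  exactly conserved.
* **ATPase**: a Hill function of ATP (K = 2.5 mM, n = 6) lumping
  maintenance and anabolic demand. A first-order law here drains the
  adenylate pool within seconds once famine cuts glycolytic ATP
  production; the Hill form shuts demand off at low energy charge and
  keeps famine ATP near 1.2–1.5 mM, which matches the observed phenotype
  (ATP *rises* after the pulse).
* **Glycogen synthesis/degradation**: piecewise-linear interpolated base
  fluxes over cycle time (shipped as CSV tables), times UDPG saturation
  (Ksat = 0.1 mM, the documented configurable default) and the capacity
  factor; degradation saturates in glycogen (Ksat = 5 mM). During the
  chemostat phase the tables are replaced by their cycle means — a
  periodic forcing admits no steady state.

### The ¹³C layer

Each carbon species gets a labelled twin; every transport/reaction term
of the total balance reappears multiplied by the enrichment
(labelled/total, 0 for an empty pool) of the species donating carbon to
that term, with reversible fluxes split as `v⁺ = max(v,0)`,
`v⁻ = max(−v,0)`. Positional isotopomers are not tracked; this is valid
precisely because only enrichment is compared. Two bookkeeping rules keep
labelled carbon conserved in glucose-equivalents at the only
carbon-count-changing reactions: the aldolase cleavage passes the FBP
enrichment to both trioses (and the reverse reaction averages the triose
enrichments), and trehalose-6-phosphate synthase averages the G6P and
UDPG enrichments (trehalose species count as two glucose-equivalents).
Cofactors and phosphate carry no label. The enrichment stage runs one
labelled cycle (configurable) after the 20 unlabelled ones, with 99% of
feed glucose labelled.

## 2. The protocol and its parameters

| parameter | default | unit | why |
|---|---|---|---|
| dilution rate D | 0.1 | 1/h | the experimental chemostat rate |
| cycle length | 400 | s | experimental cycle |
| feed window | 20 | s | block feed |
| feed multiplier | 20 | — | same average supply as the chemostat |
| outflow end | 260 | s | fed volume withdrawn at constant rate by ~260 s |
| cycles | 20 | — | experimental/simulated cycle count |
| chemostat feed | 36.2 | g/L | solved at design time (below) |
| biomass | 10.5 | gDW/L | chosen with the feed so the cycle reproduces the printed glucose window |
| vacuole fraction | 0.1 | of cytosol | not reported; configurable |
| label fraction | 0.99 | — | enrichment-stage feed |

The feed concentration and biomass are the two protocol-level constants
the source never prints. They are pinned jointly by three printed
anchors: residual glucose ≈ 0.1 g/L, maximal glucose ≈ 0.45 g/L within
the cycle, and uptake ≈ 0.72 mM s⁻¹ at 20 s. With the supply-balance
identity `Cs = GLCec,ss + φ·v_ss/D` these leave one free choice (the
steady-state uptake, set to 0.265 mM s⁻¹), and the implied apparent yield
(~0.3 gDW/g) is plausible for cells paying extra maintenance under
perturbation.

Phases are integrated separately (feed/outflow/batch) so no solver step
straddles a discontinuity; the outflow rate is constant — the simplest
reading of "emptied by approximately 260 s" — which closes the broth
volume each cycle to machine precision by construction.

## 3. Parameter design: how the shipped sets were made

The appendix-level rate equations and the full parameter table of the
source are not printed; only the adaptation table (HXT Vmax 8.13→1.70,
Km 1.01→0.90; HXK/GLK Vmax 6.25→15.75, Km 0.35→0.11, Ki,T6P
0.0073→0.0183) and a handful of anchors are. The shipped sets were
therefore *designed* (script in `data-raw/design_params.R`):

1. Fix a chemostat steady state: literature-flavoured concentrations and
   a flux distribution that closes every internal balance exactly
   (uptake 0.265, storage turnover ~8% of supply through glycogen and
   ~4.5% through the trehalose cycle, lumped TCA/PPP/biomass sinks).
2. Fix the printed kinetic constants, plus affinity constants chosen for
   ~10-fold excess capacity in lower glycolysis (saturation ≈ 0.1 at
   steady state) — the feast transient runs at 3–4× the steady flux and
   must pass through promptly.
3. Solve every remaining Vmax-class constant linearly from its rate law
   at that state; solve GLCi from the HXK law and GLCec from the HXT law
   (their Vmax values being printed, not free).
4. Simulate the cycles and iterate the handful of genuinely free
   constants (HXT Ki; slow-pool targets) against the printed anchors.

The designed state is an exact fixed point (residual ~1e-14 mM/s), which
is what the steady-state residual test checks.

Two design iterations deserve an honest account:

* **Slow pools sit at the cycle attractor.** Storage-branch pools
  (glycogen, vacuolar and extracellular trehalose, glycerol) relax over
  hours; if the chemostat state differs from the feast/famine attractor,
  20 cycles cannot converge to a limit cycle. The design therefore sets
  those targets at the attractor's cycle-end values (found by fixed-point
  iteration: simulate, read off, re-design). A corollary worth stating:
  cytosolic trehalose in the cycling regime is a few tens of µM — far
  below the vacuolar pool — which reproduces the source's own observation
  that MM trehalase kinetics force "artificially low" cytosolic
  trehalose.
* **T6P level and identifiability.** The steady T6P was first set to
  1 mM; at that level the T6P term dominates the HXK denominator
  (T6P/Ki ≈ 55) and cycle data identify only the Vmax/Km *ratio* of
  HXK — exactly the parameter dependency the source combats with
  regularization. The shipped design uses a literature-realistic cycle
  T6P scale (~0.01–0.1 mM), which restores curvature. Even so, HXK runs
  at 2–4% substrate saturation at the printed Vmax, so Km,GLC and
  Ki,T6P remain structurally unidentifiable from cycle data (only ratios
  are constrained); the default recovery experiment therefore frees
  {HXT.Vmax, HXT.Km, HXK.Vmax}, all identifiable, and this limitation is
  a finding, not a bug — it mirrors the dependency discussion that
  motivated the two-step pipeline in the first place.

The reference (pre-adaptation) set differs from the calibrated set in the
printed adaptation-table values plus NTH1 affinity (Km 2.11 mM) and a
40%-higher maintenance ATPase (the source states maintenance decreased
under adaptation without printing the value). The reference chemostat
steady state exists and is positive but is a weakly unstable focus — the
un-adapted parameterization oscillates under chemostat conditions, which
is why `run_chemostat()` polishes with a root-finder rather than relying
on forward integration alone.

## 4. Numerical choices

* **Integrator**: RODAS3 (4-stage Rosenbrock, order 3(2), stiffly
  accurate, L-stable) with finite-difference Jacobians and cubic Hermite
  dense output, in C++. Defaults rtol 1e-8, atol 1e-10 mM (trehalose/T6P
  pools span four orders of magnitude); estimation uses rtol 1e-6.
* **Nonnegativity**: rate laws clamp concentrations at zero (Rosenbrock
  stage states may probe slightly negative); accepted steps that would
  undershoot below −1e-7 mM are rejected and retried with half the step,
  smaller undershoot is clipped (counted), and anything below −1e-4 mM
  aborts the integration. A stricter clip threshold (1e-9 mM) thrashes to
  a standstill near the zero-asymptotes of small pools.
* **Steady-state search**: forward integration to settle, then damped
  Gauss–Newton (Marquardt damping, QR solves on the damped augmented
  system) on the reduced system with the two moiety totals and the broth
  volume eliminated. Plain Newton overshoots (state scales span seven
  decades) and normal equations square an already severe condition
  number.
* **Estimation**: bounded Levenberg–Marquardt in log10-parameter space
  (positivity and scale invariance; box ±2 decades around the reference),
  finite-difference step 1e-3 decades — large enough to sit above the
  integrator's error floor. Simulation failures at trial parameters
  return large finite residuals so the optimizer retreats. The L1 penalty
  enters as one residual `sqrt(λ·|Δlog10 θ|)` per free constant, making
  the cost decomposition `error = error_data + λΣ|Δlog10 θ|` exact. The
  penalty is applied to log-deviations, not raw differences: free
  constants span four decades and raw-unit penalties would weight Vmax
  against Ki absurdly. (The source's cost-function equation carries a
  negative sign on the penalty term; a cost must be non-negative, so the
  penalty is implemented as written here.)
* **Fitting simulations** run 2–3 cycles from the shipped steady state
  rather than the full 20 — the observables of the compared cycle are
  within noise of the converged ones, at an order of magnitude less cost.
* **Degenerate inputs**: all-zero capacities freeze the state; empty
  observation tables are valid; a transporter with zero capacity makes
  the chemostat starve, which `run_chemostat()` reports as a convergence
  error.

## 5. The synthetic-data generator: what a green test establishes

`generate_bundle()` emulates the *statistical structure* of the real
datasets: denser sampling in the first ~100 s (default every 5 s, then
every 25 s), multiplicative log-normal noise with CV 5% on concentrations
and 10% on fluxes (sd column = CV × value), absolute noise of 3
percentage points on enrichment truncated to [0, 100], and flux
observations reported as piecewise-linear resamplings over 25-s nodes —
the shape in which rates reconstructed from isotope data actually arrive.
The noise CVs are documented choices (the source reports no error model).
Fixed seeds give bitwise-reproducible bundles.

What it does **not** emulate: real analytical error structure
(correlated, heteroscedastic beyond the CV model), sampling-device
artefacts, natural-abundance corrections, raw spectra, or biological
replicate variation. A green recovery test therefore establishes that the
pipeline identifies the adapted constants *given the model family is
correct and noise is as configured* — a statement about the estimator,
not about nature.

The recovery experiment's ground truth defaults to the calibrated set —
i.e. the headline adaptation (HXT down 0.21×, HXK/GLK up 2.5×) is the
recoverable signal, and fits start from the reference values, exactly the
situation of the original calibration.

## 6. The feasibility scan and ensembles

The passive-transport scan clamps extracellular glucose to a converged
cycle trace (residual ~0.1, peak ~0.45 g/L), switches sensing off, draws
HXT constants log-uniformly over ±3 decades around the estimates, and
re-simulates the intracellular model per sample (three clamped cycles, so
the intracellular state converges before uptake is read at 20 s and
400 s). The negative result is mechanistic: any passive parameterization
strong enough to reach 0.72 mM s⁻¹ at 20 s keeps importing at ≥0.2 mM s⁻¹
at 400 s, because end-of-cycle glucose (~0.5 mM) still drives the carrier
and intracellular demand never drops to zero. The sensing threshold — and
nothing else in the sampled space — produces the (high, ≈0) pair.
"Almost zero" is implemented as ε = 0.02 mM s⁻¹, configurable.

Ensembles draw all constants uniformly from ±r (default 10%); the
3-decade scan draws log-uniformly, matching each range's semantics.
Dispersion is summarized per variable as the median over the cycle of the
ensemble SD normalized by the profile's scale (max |ensemble mean|);
pointwise-relative dispersion would diverge wherever famine drives a flux
to zero, regardless of actual consistency. Under this measure flux
profiles disperse less than concentration profiles — the homeostatic
claim restated as an assertable comparison. Uniform Vmax scaling is
covered by an exact homogeneity check plus ratio invariance of the core
chain between the calibrated and a +10%-scaled steady state; larger
uniform scalings fold the sensing-limited chemostat uptake branch away
entirely (there is no steady state at 2× capacity), a real bifurcation of
this model worth knowing about.

## 7. Known limitations

* Rate laws for the canonical glycolytic enzymes follow standard families
  (reversible MM / MWC / Hill) with constants designed, not fitted to
  enzyme data; the appendix-level equations of the source are not public.
* Glycogen kinetics are phenomenological forcings; the enrichment of
  storage pools therefore relaxes on the forcing's schedule, and
  glycolytic enrichment decays strongly late-cycle as (mostly unlabelled)
  storage carbon takes over the inflow — the same caveat the source
  reports for its own simulations.
* Within-cycle peak times: hexose phosphates peak early (<30 s), BPG at
  ~150–170 s, PEP at ~210–230 s; the lower-glycolysis pattern is
  reproduced as windows, not to the printed second, and P3G's feast spike
  exceeds its late hump.
* Km,GLC and Ki,T6P of HXK/GLK are not identifiable from cycle data at
  the printed Vmax (§3); estimates of them are regularization-dominated.
* The un-adapted (reference) chemostat is oscillatory; its steady state
  is meaningful only as a fixed point.
* No gas phase, pH, dissolved O₂, growth within cycles, SBML interchange,
  or positional isotopomers.
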
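---
title: "A modular multi-level model of exercising human skeletal muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A modular multi-level model of exercising human skeletal muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclesim)
```

# Scope and architecture

`musclesim` simulates human skeletal muscle (a 5 kg wet-weight two-leg
lump, as engaged on a cycling ergometer) across four coupled levels:

1. **Physiology** — capillary blood flow and muscle volume responding to
   the work rate; a single capillary + interstitial "blood" compartment
   exchanging nine species (O2, CO2, glucose, lactate, pyruvate,
   alanine, glycerol, free fatty acids, protons) with the fibers.
2. **Transport** — passive (diffusive) and facilitated (carrier) fluxes
   between blood and cytosol and between cytosol and mitochondria, per
   fiber type.
3. **Metabolism** — a reduced two-fiber-type energy-metabolic core:
   glycogenolysis, glycogen synthase, lumped glycolysis, lactate
   dehydrogenase, alanine transaminase, lipolysis and fatty-acid
   activation, creatine kinase (CK) and adenylate kinase (AK), ATPase,
   pyruvate dehydrogenase + TCA, beta-oxidation, and oxidative
   phosphorylation with explicit proton bookkeeping.
4. **Signalling and gene expression** — myoplasmic Ca²⁺ →
   calmodulin → {CaMKII, calcineurin → CRTC, CaMKK2}, the three AMPK
   heterotrimers (α2β2γ1, α2β2γ3, α1β2γ1) regulated by LKB1, CaMKK2 and
   free AMP/ATP, CREB1 Ser133 phosphorylation, and a
   constitutive-plus-activated transcription model for the early genes
   *NR4A2*/*NR4A3*, a generic early transcription factor X, and the
   delayed gene *PPARGC1A* driven by the accumulated protein of X.

The model is not written as one monolithic ODE file.  Each level is a
*module* with typed ports (`input`, `output`, `contact`); modules are
wired by directed/undirected connections and named buses, and
[mm_flatten()] collapses the graph into one flat hybrid ODE system by
union-find over connected variables.  The default assembly has
14 modules and `r ode_count(mm_flatten(build_model()))` state variables.
The two fiber branches are built by the same constructors and differ
only in parameter values, which a test asserts structurally.

# The activation formalism

Exercise enters every flux through the multiplicative activation
factor

$$a(t) = 1 + \alpha\,W\,\bigl(1 - e^{(t_{start}-t)/\tau}\bigr),$$

with activation coefficient $\alpha$ (1/W), time constant $\tau$ (min)
and the relevant work rate $W$ (total power for blood flow and volume,
per-fiber power for intracellular fluxes).  Inside simulations this
closed form is realised as a first-order state
$\dot a = \bigl((1+\alpha W(t)) - a\bigr)/\tau$, which is identical to
the closed form for constant $W$ applied from $t_{start}$ and extends it
continuously to stepwise protocols: after each power change the factor
relaxes to the new asymptote $1+\alpha W_{new}$ with the same $\tau$
(symmetric first-order response).  A test verifies the ODE realisation
against the closed form.

Key physiological constants: resting blood flow $Q_0 = 0.9$ L/min for
both legs, resting muscle volume 5 kg w.w. with
$V_{bl} = 0.2\,V_{mus}$, $\tau_Q = \tau_V = 0.4$ min; fiber volumes
$V_I = V_{II} = 2$ kg w.w. with cytosolic fractions 0.88 (type I) and
0.92 (type II).

# Protocols and recruitment

Three protocol generators cover the standard designs: an incremental
ramp (default 10 W/min) terminating at exhaustion, square-wave
intervals (work:recovery in seconds, e.g. 16:32 at 250 W peak), and
continuous constant-fraction-of-VO2max bouts.  Total power splits into
fiber-type contributions by a piecewise-linear recruitment rule: all
power to type I below the type-II onset threshold (24% of
$W_{max} = 250$ W, reached at minute 6 of the default ramp), then a
linear split such that both types reach their caps (125 W + 125 W)
together at $W_{max}$; reaching full recruitment defines exhaustion.
Whether type-I power tracks the total or rises linearly below threshold
is not constrained by the recruitment data we mirror; the
piecewise-linear rule was chosen for continuity and for reproducing the
125/125 W caps, and is a modelling choice.  Optional fatigue is a
prescribed linear decline of type-II power within each work bout —
deliberately *not* a mechanistic fatigue model.

# A rest-balanced reduced metabolic core

The full published kinetics of muscle energy metabolism run to
hundreds of parameters; this package implements a structurally faithful
reduced core (about twenty reactions per fiber) whose rate laws are
products of normalised Michaelis–Menten factors,

$$v = J_{rest}\; a(t) \prod_k \frac{C_k/(K_k + C_k)}{C_k^0/(K_k + C_k^0)},$$

anchored so that every factor equals 1 at the configured resting
concentrations.  `derive_parameters()` then solves the resting flux
routing exactly: the resting NADH turnover follows from the ATP
balance, pyruvate production matches oxidation plus lactate, alanine
and pyruvate release, every transport coefficient is sized to carry its
resting flux down the configured gradient, and arterial concentrations
close the blood balance.  The shipped resting state is therefore an
exact steady state *by construction* (the package verifies residual
derivatives below 10⁻⁶ mmol kg⁻¹ min⁻¹, and in practice they are at
machine precision).  The `RateLawConfig`-style schema (per-reaction
`Vmax`/`KM`/activation entries) is expressive enough to host a full
kinetic parameterisation later.

Choices worth knowing:

* **Free nucleotides.** ADP and AMP states are kept near the CK/AK
  equilibria by fast mass-action CK and AK reactions; the signalling
  level independently computes free ADP/AMP from the equilibrium
  formulas (`free_adp_amp()`), and the two agree in simulation.  The CK
  forward rate carries an $H/H^0$ factor, so acidosis shifts the
  equilibrium toward ATP, and PCr recovery tracks pH recovery — both
  physiologically sensible consequences.
* **Respiratory control.** Oxidative phosphorylation is driven by NADH,
  O2, Pi and a cubic factor in normalised free ADP.  The steep ADP
  dependence is what lets the model repay the phosphocreatine debt
  after exercise at near-resting activation (excess post-exercise
  oxygen consumption); with a first-order dependence the debt is repaid
  too slowly and signalling baselines are not recovered within an hour.
  PDH and beta-oxidation carry a first-order ADP factor for the same
  reason.
* **Proton bookkeeping.** Lactate production adds one H⁺, ATP
  hydrolysis adds 0.3 H⁺, oxidative fluxes consume H⁺ with a
  stoichiometry chosen to close the resting proton balance.  Protons are
  buffered (β = 22 mmol kg⁻¹ per pH unit in muscle, 25 in blood):
  the raw proton flux is converted to
  $\dot H = \ln(10)\,H\,\Phi/\beta$.  Proton export rides on lactate
  (monocarboxylate co-transport, 1 H⁺ per lactate) plus a lumped
  acid extruder that is flux-free at the resting transmembrane pH
  gradient and activates as the cytosol acidifies.  Blood carries acid
  on buffers: the arterial wash-out term for H⁺ is scaled by a carriage
  factor (2.5 × 10⁵ buffered-acid equivalents per unit free-H⁺
  arterial–venous difference), without which no physically possible
  free-H⁺ gradient could remove the resting lactate-coupled acid load.
* **Effective O2 pools.** Cytosolic and mitochondrial O2 are effective
  (myoglobin-buffered) pools with shallow resting gradients, giving the
  O2 conductances the headroom that hemoglobin/myoglobin carriage
  provides in vivo; O2 delivery from blood remains flow-limited and
  activation-scaled.

With the frozen defaults, 30 min at 70% VO2max ends with PCr at ~72%
(type I) and ~71% (type II) of rest, lactate ~2.3/4.1 mmol kg⁻¹,
muscle pH ~7.00/6.98, ATP essentially constant, and free AMP up
3–4-fold — the qualitative pattern expected at moderate intensity.

# Signalling calibration

All signalling rate constants are calibration parameters.  The
calibration targets are the printed phosphorylation fractions at the
end of 30 min at 70% VO2max: ~30% of the γ3-containing heterotrimer
and ~10% of all α2-containing AMPK phosphorylated, with the two
γ1-complexes almost unchanged from baseline.  The heterotrimer pool
shares default to 65% α2β2γ1, 20% α2β2γ3, 15% α1β2γ1 (in line with
human vastus lateralis proteomics); with those shares the 10%/30% pair
forces the γ1-complex response to stay near its ~3–4% baseline, which
the parameterisation delivers.  The γ3 complex gets its exercise
responsiveness mainly from a large CaMKK2 coupling (Ca²⁺-driven) plus
AMP protection against dephosphorylation with a protection constant
well above resting AMP; this combination reproduces the 30% end-bout
fraction *and* lets the fraction return to within 1% of baseline an
hour after exercise, because the calcium input deactivates quickly
while the AMP tail decays with the phosphocreatine debt.  Baseline
activity of α2β2γ3 is set below the other two complexes, and whole-cell
AMPK activity is the sum over heterotrimers.  These defaults were tuned
once against the targets and frozen; they are ordinary config entries,
and the acceptance script recomputes the fractions from scratch on
every run.

CaMKII, calcineurin→CRTC and CREB1 use standard
kinase/phosphatase balances on conserved totals; the closed-form fixed
point $P/T = k_{on}/(k_{on}+k_{off})$ (`phospho_steady_state()`) is
used both for initialisation (the resting state is the exact fixed
point) and as the test oracle.  CRTC reactivation is the slowest
signalling time constant (~7 min) — slow enough to let early-gene
transcription integrate the exercise bout, fast enough that every
signalling state is back within 1% of baseline one hour after
exercise, which a test asserts.

# Gene expression

Each gene has a constitutive transcription rate $k_0$ (mRNA in
baseline-normalised units, so resting fold change is exactly 1) plus an
activated term $V_{max}\,\mathrm{Hill}(d - d_0)$ on the *excess* of the
drive over its resting value.  Early genes and factor X are driven by
the product (CREB1-p/ref) × (CRTC-active/ref) — multiplicative
coactivator logic, a design choice where only "CREB- and CRTC-related
expression" is constrained.  *PPARGC1A* is driven by the accumulated
protein of X, translated from X mRNA with a slow protein decay
(t½ ≈ 1.4 h).  Degradation constants default to values that place the
simulated whole-muscle *PPARGC1A* peak 3–4 h after exercise and the
NR4A peaks within the first post-exercise hour.  In the default
calibration the NR4A mRNAs peak essentially at exercise termination:
with first-order transcription/decay a strictly interior post-exercise
peak would require a drive that keeps rising after the stimulus ends,
a promoter/processing delay the model deliberately omits.

Two model variants are exposed: `genes$x_factor_enabled = FALSE`
silences X translation (the delayed *PPARGC1A* response collapses to
its constitutive level — the in-silico test of the intermediate-factor
hypothesis), and `genes$direct_creb_regulation = TRUE` drives
*PPARGC1A* directly from CREB1/CRTC (its response then peaks early,
within ~2 h, illustrating why the intermediate factor is needed to
produce a delayed peak).  X is a single generic species; candidate
identities (AP-1 family, EGR1, MYC) are a matter for the literature,
not for this code.

# Numerics

The flat system is integrated with the VODE stiff BDF solver
(`deSolve::vode`, `mf = 22`, internally generated Jacobian), default
tolerances rtol 10⁻⁸ / atol 10⁻¹⁰; a test verifies that halving both
tolerances changes trajectories by well under 0.1%.  Integration
restarts at every protocol discontinuity so no bout edge is stepped
over (numerically coincident edges are merged at 10⁻⁷ min).  Discrete
events support time triggers and root-crossing triggers; simultaneous
events execute in module-name order.  The right-hand side is generated
once by code generation from the flat model, with assignments
topologically sorted.  Everything is deterministic — repeated runs are
byte-identical, which a test asserts.

Merged variables must agree on initial values (variables behind input
ports yield to their driver) and on non-empty unit strings; conflicts
are errors rather than silent choices.  Flat variables take the
lexicographically first qualified name, with all aliases kept in the
provenance map (`flat_name()` resolves any alias).

Problem sizes used by the test-suite and acceptance runs: 137 state
variables; 30-min bouts with 60-min recovery on a 0.5-min output grid;
the gene-expression horizon is 60 min of exercise plus 6 h of recovery
on a 1-min grid; interval fixtures use 4–6 bouts on a 0.02-min grid.
A 30-min moderate-intensity run completes in a few seconds on one CPU.

# Text formats

The package owns a small text-notation layer: Transpath-style species
strings (`"A:B"`, `"A{p}"`, `"(A)3"`, `"(A{p})3:B{r}{p}:C"`; states are
opaque ordered labels, multimers of complexes are accepted as the
natural grammar closure) with a verified parse/emit round trip, and
`@entity_id.property = value` annotation lines whose non-annotation
content passes through untouched for a downstream host-language parser.
Flat models export to SBML L3V2 (species, parameters, static
compartments, reactions with MathML kinetic laws, rules, events) with a
structural consistency check and a verified export→import→simulate
round trip.  Constructs with no SBML counterpart — closure-valued
module functions such as protocol drivers, buffered species,
dynamically sized compartments — raise before writing, so the assembled
muscle model itself is reported as non-exportable rather than exported
lossily.  Protocol tables (`time,power` CSV/TSV) load as
piecewise-constant steps by default (spline opt-in) with boundary
clamping.

# Limitations

* The metabolic core is reduced: no TCA intermediates, no
  malate–aspartate shuttle, lumped redox, integer-lumped stoichiometries
  for fat oxidation.  Quantities it was not calibrated against (e.g.
  absolute glycogen depletion rates) should be read qualitatively.
* Hormonal regulation, feeding state, temperature and central (CNS)
  factors are outside the model; fatigue is a prescribed power decline,
  not a mechanism.  Post-exercise glycogen resynthesis sits between
  fasted and fed literature values and was not tuned to either.
* Arterial concentrations are constant boundary conditions; the
  cardiorespiratory system is lumped into the blood-flow activation.
* Calcium magnitudes, protein totals and all signalling rate constants
  are assumptions or calibration products, documented in
  `default_config()`; they are constrained by the reproduced
  phosphorylation fractions and timing patterns, not by direct
  measurement.
* Subcellular localisation of CaMKII/AMPK is not modelled.
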
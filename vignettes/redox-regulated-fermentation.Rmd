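---
title: "Modeling oxygen-dependent redox regulation of E. coli fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling oxygen-dependent redox regulation of E. coli fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxferm)
```

## The modeling problem

*Escherichia coli* switches its catabolism with oxygen availability. Under
full aeration, glucose is respired: NADH formed in glycolysis, by pyruvate
dehydrogenase (PDH) and in the TCA cycle is reoxidized by the NADH
dehydrogenases Nuo and Ndh, which reduce the membrane quinone pool; the
terminal oxidases cytochrome *bo* (Cyo, low oxygen affinity, high rate) and
cytochrome *bd* (Cyd, high affinity, lower rate) reoxidize quinol with
oxygen, and the pumped protons drive ATP synthesis. As oxygen falls, the
quinone pool goes reduced, the NADH/NAD⁺ ratio rises, and carbon overflows
into the mixed-acid fermentation products: lactate (LDH), ethanol
(ALDH/ADH, consuming two NADH per ethanol), acetate (Pta–Ack, yielding
ATP), formate (pyruvate formate-lyase, Pfl) and succinate (the reductive
branch PEP → OAA → malate → fumarate → succinate, ending in fumarate
reductase, Frd).

Two global regulators coordinate the switch. Fnr senses cytoplasmic oxygen
directly and is active only near anaerobiosis. ArcB autophosphorylates when
the oxidized quinone level is low — oxidized quinone inhibits the
autophosphorylation — and then phosphorylates ArcA; active ArcA represses
*cyoABCD*, PDH and TCA-cycle genes and activates *cydAB* and *pfl*, while
Fnr activates *frd* and *pfl* and represses *cydAB*, *ndh* and TCA genes.
`redoxferm` turns this picture into a simulatable batch-fermentation model
whose single controlled boundary condition is the dissolved-oxygen (DO)
setpoint, expressed in percent of air saturation at 37 °C.

## Model structure

**States.** Extracellular: glucose, the five products (g/l) and biomass
(gDW/l). Intracellular (mmol/gDW): the glycolytic, TCA/glyoxylate and
pentose-phosphate intermediates. Two conserved cofactor pairs: NADH/NAD⁺
and Q/QH₂; only one member of each pair is integrated, the partner is
`total − tracked`, so conservation is exact by construction. Cytoplasmic
oxygen is algebraic, `[O2] = k_O2 · (DO/100) · [DO2]*`, with `k_O2 ≤ 1`
because the cytoplasm is at most at the medium concentration; there is no
mass-transfer ODE because every experiment in scope holds DO at a setpoint.

**Transcription factors.** Both activities are algebraic Hill functions
with a shared negative coefficient (quasi-steady phosphorelay and Fe–S
chemistry): activity ½ at the affinity constant, → 1 at zero ligand.
They are evaluated through the equivalent singularity-free form
`K^|n|/(K^|n| + x^|n|)`, which avoids `0^negative` at anaerobiosis. Each
regulation edge contributes a factor `(1 + a·TF)` (activation) or
`1/(1 + r·TF)` (repression) to the target reaction's maximal rate; factors
multiply across edges, and `f(0) = 1` so the unregulated model is recovered
exactly when both activities vanish.

**Kinetics.** Rate laws are declared per reaction in the network file, from
a small registry: irreversible multiplicative Michaelis–Menten (optionally
with per-substrate Hill exponents), mass-action-ratio reversible MM,
a two-way MM difference (malate dehydrogenase, whose direction follows the
NADH/NAD⁺ state), and a lumped phosphotransferase form in which glucose
uptake is driven by the PEP/PYR phosphorylation potential. Effector
factors: activation `(1 + β·A/(K_A + A))`, inhibition `1/(1 + I/K_I)`, and
a redox-ratio activation `R^h/(K^h + R^h)` on `R = NADH/NAD⁺`. The named
allosteric interactions (FBP → Pyk, FBP → Ppc, PEP ⊣ Pfk) are present; in
addition the fermentative branch carries redox-ratio activation on ALDH and
on Pfl and cooperative (Hill-2) pyruvate kinetics on LDH and Pfl. These
choices encode anaerobic induction at the kinetic level and are what gives
the knockouts their characteristic lactate peak structure; they are part of
the refit model structure, documented here because the canonical kinetic
forms of the source supplement are not reproduced verbatim.

**Electron bookkeeping.** Nuo and Ndh reduce the tracked quinone pool; Cyo,
Cyd and Frd oxidize it. SDH's FAD-derived electrons are not tracked — the
oxidative-phosphorylation formula credits only Nuo, Cyo and Cyd, so routing
SDH quinol into the pool would create energy the ATP accounting never sees.
Consequently, at a quasi-steady pool, `v_Nuo + v_Ndh = v_Cyo + v_Cyd +
v_Frd`, which reduces to the textbook identity `v_Nuo + v_Ndh = v_Cyo +
v_Cyd` whenever fumarate reductase is silent (aerobic conditions, or the
*fnr* knockout). Anaerobically the chain NADH → Nuo/Ndh → QH₂ → Frd →
succinate is exactly how the reductive branch consumes NADH, which keeps
the printed NADH balance (which has no Frd term) correct.

**Physiology.** `OP = (4 v_Nuo + 4 v_Cyo + 2 v_Cyd)/3` (H⁺/e⁻ ratios 2, 2,
1; H⁺/ATP = 3); `v_ATP` adds the substrate-level terms and subtracts the
ATP-consuming reactions; growth is strictly `μ = k_ATP · v_ATP`, floored at
zero. Biomass formation drains its carbon from G6P at `μ · c_X` gC/gDW/h
(carbon content `c_X` = 0.48 gC/gDW), through a saturable factor
`G6P/(G6P + 0.005)` so the drain vanishes with the pool; all other
precursor requirements are absorbed into the fitted maximal rates. NADPH
production is reported diagnostically only — the printed balance has no
consumption term, and we did not invent a sink.

## Numerical choices

The batch system is integrated with `deSolve::lsodar` (adaptive,
stiff-capable, with root finding); glucose depletion is an event located to
solver precision at a configurable threshold (default 0.01 g/l). A DO
switch restarts the integration at the discontinuity — transcription-factor
activities are algebraic, so a hard switch is well posed and reproducible.
Default tolerances are `rtol = 1e-8`, `atol = 1e-10`; halving them changes
final product concentrations by less than 1e-4 relative (tested). Rates are
evaluated clamp-free except that solver trial steps probing marginally
below zero are treated as zero; a concentration below −1e-6 aborts the run
as an integrator failure, and accepted trajectories are verified
non-negative. Everything is deterministic: no seeds are consumed anywhere.

Cumulative CO₂ and cumulative biomass-drain carbon are integrated alongside
the state, so batch carbon balances close exactly rather than by
quadrature; the shipped tests require closure to 1e-3 on every completed
batch (the slack covers the saturable-drain approximation, not quadrature
error).

## Parameter provenance and calibration

The canonical parameter values of the source model were not available to
this implementation, so the shipped CSV is a *refit* set (every row is
flagged `provenance: refit`). It was calibrated, once, against the
study-level behavior the model is known to produce: aerobic physiology
(μ ≈ 0.68 h⁻¹, qOUR ≈ 18 mmol O₂/gDW/h, acetate overflow), the wild-type
DO sweep (formate/ethanol/succinate rising as DO falls, lactate rising and
then collapsing below ~5% DO, acetate the primary product above 15% DO,
lactate the least abundant product below 2% DO), the knockout sweeps
(*fnr*: lactate peaking at 3% DO with succinate essentially absent; *arcA*:
lactate peaking at 4% DO with ethanol above the wild type below 6% DO;
*pfl*: no formate, lactate-dominant), and the dual-phase lactate design for
the *pfl* knockout. Condition-category boundaries (7%, 20%) label sweeps
for reporting only; no model behavior switches on them.

The cultivation protocol defaults are part of these study conditions:
10 g/l glucose, inoculum 0.035 gDW/l, depletion threshold 0.01 g/l. The
dual-phase design (40% → 1% DO) then gives a micro-aerobic-throughout
productivity of 0.385 g/l/h at yield 0.71 g/g, and an optimum of
0.694 g/l/h at a switching time of 4.0 h. Against the reported design
study, the baseline and the switching time agree closely while the optimal
productivity is underpredicted by about 14%: the refit micro-aerobic
lactate yield (0.71 g/g) sits below the ~0.88 g/g the reported optimum
implies, a known limitation of this parameterization rather than of the
model structure. The acceptance tests state these bands explicitly.

## What the tests do and do not show

The property suite asserts conservation (pool sums exact, carbon closure),
the regulatory identities (Hill equivalence to 1e-12, factor
multiplicativity, knockout idempotence/commutativity), the derived-rate
equations against independent stoichiometric dot-product oracles, exact
linearity of growth in ATP production, event-location accuracy,
determinism, and a closed-form steady-state oracle: a three-metabolite toy
pathway with one conserved cofactor pair and one regulated step, whose
fixed point is solved analytically and must be met to 1e-8 even with the
cofactor cycling stiffened 1000-fold. A golden-regression table of
canonical strain × DO runs, stamped with a locale-independent parameter
digest, guards refactors at 1e-6 relative.

Passing these tests shows that the implementation integrates *this* model
correctly and that the refit set reproduces the *in-silico* study's
structure. It does not validate the model against new experimental data:
extracellular measurements enter only through the calibration targets
above, fed-batch/continuous operation, pH and temperature effects and
NADH allosteric inhibition of PDH/CS/ICDH are out of scope, and the
ethanol response of the *arcA* knockout at full anaerobiosis is expected to
overshoot reality because that inhibition is absent.

## A short tour

```{r eval = FALSE}
library(redoxferm)

net <- ecoli_network()
par <- default_parameters()

# wild-type batch at 3% DO (condition II: both Fnr and ArcA active)
tr <- simulate_batch(cultivation_protocol(do = 3), net, par)
products_at_depletion(tr)
carbon_balance(tr, net)

# knockout sweep and peak localization
sw <- do_sweep(strain = "arcA", network = net, params = par)
find_peak(sw, "lactate")

# dual-phase lactate design for the pfl knockout
sc <- dual_phase_scan(strain = "pfl", do_aero = 40, do_micro = 1,
                      network = net, params = par)
optimal_switch(sc)
```
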
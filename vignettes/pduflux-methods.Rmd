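---
title: "Models and methods behind pduflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pduflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pduflux)
```

## The pathway model

`pduflux` quantifies glycerol biotransformation by resting *Lactobacillus
reuteri* cells through the propanediol-utilization (Pdu) pathway. Four net
specific fluxes (mmol/g_CDW·h; consumption negative) connect the C3
backbone:

* `v1`: glycerol → 3HPA, the B12-dependent glycerol/diol dehydratase
  (PduCDE);
* `v2`: 3HPA + NADH → 1,3PDO + NAD⁺ (PduQ / alcohol dehydrogenase);
* `v3`: 3HPA + NAD⁺ → 3HP + NADH + ATP, lumping the three oxidative steps
  (PduP → 3HP-CoA, PduL → 3HP-phosphate, PduW → 3HP). The acyl
  intermediates and CoA cycle internally and carry zero net coefficients;
  they are kept in the metabolite table for documentation only, because
  their concentrations are not observable in broth samples.
* `v4`: net accumulation of extracellular 3HPA. This is a bookkeeping
  pseudo-flux, not an enzymatic step: it is defined by the node balance
  `|v1| = v2 + v3 + v4` and its stoichiometric column touches only 3HPA.

Two structural facts drive everything else. First, resting cells neither
grow on glycerol nor possess another redox sink for this pathway, so the
NAD⁺/NADH pair cycles strictly between the two branches: at cofactor
quasi-steady state `v2 = v3` and the products are equimolar. Second, the
node balance plus this redox constraint make the branch fluxes identifiable
from bulk measurements alone:
`v2 = v3 = (|v1| − v4)/2` ([infer_branch_fluxes()]). The flux split ratio
around the node, `100·v3/(v2+v3)` to 3HP and `100·v2/(v2+v3)` to 1,3PDO,
is therefore 50/50 mol% whenever the cofactor pool is at quasi-steady
state.

The five enzymes of the pathway map onto four net fluxes because the
oxidative branch is lumped; a fifth per-enzyme rate label is therefore not
housed in the network and would be indistinguishable from `v3` with broth
data.

Sign convention: consumption fluxes are stored negative, matching how
specific consumption rates are conventionally tabulated; all balance
algebra uses magnitudes explicitly. Unit bridges use fixed two-decimal
molar masses (glycerol 92.09, 3HPA 74.08, 3HP 90.08, 1,3PDO 76.09,
carbohydrazide 90.09 g/mol), configurable only through a network
definition file.

## Rate equations

Rates are estimated from windowed differences of measured samples:

* batch (constant volume): `Q = (P_f − P_i)/Δt` in g/L·h and
  `q = 1000·Q/X` in mg/g_CDW·h with `X` the cell density (g_CDW/L);
* variable-volume fed-batch: production `rate = (P_f·V_f − P_i·V_i)/Δt`
  and consumption `rate = (S_f·V_f − S_feed·V_feed − S_i·V_i)/Δt` in g/h,
  with `V_feed = F_vol·Δt`, and `q = 1000·rate/x` with `x` the total
  biocatalyst (g_CDW).

The endpoint (two-sample) form is the defining estimator; window endpoints
snap to the nearest recorded samples and are never interpolated, because
the quantities are defined on measured samples. A least-squares slope over
all samples in the window (`estimator = "regression"`) is offered as a
robustness option; on noiseless linear-phase data the two agree to well
under 1%. The consumption balance assumes one constant feed term, so a
window spanning a feed-rate change is refused rather than silently
averaged.

Two volume terms are deliberately ignored because they are not part of the
recorded protocols: sample withdrawal volumes and the volume of base added
for pH control. Both are known (small) bias sources on `V(t)` and are
documented here rather than guessed.

## The kinetic simulator

No kinetic rate laws are observable from the flux table itself, so the
simulator uses the simplest forms consistent with the qualitative
constraints of the system, with every constant exposed in
[kinetic_params()]:

* GDH: Haldane substrate inhibition in glycerol with non-competitive
  1,3PDO inhibition,
  `v1 = vmax_gdh · S/(Km_gly + S + S²/Ki_gly) · Ki_pdo/(Ki_pdo + PDO)`,
  times a smooth shut-off (logistic, width 0.2 g/L) when free 3HPA reaches
  a toxic threshold and no scavenger is active. `Km_gly` defaults to
  0.2 g/L — B12-dependent glycerol dehydratases have low-millimolar
  substrate affinities — and `Ki_gly = 150`, `Ki_pdo = 50` g/L encode the
  observed high-glycerol and 1,3PDO inhibition at plausible magnitudes.
* Branches: a shared saturable capacity
  `r = vmax_branch · A/(Km_hpa + A) · f_inh(A)` with `Km_hpa = 0.1` g/L.
  `f_inh` is a logistic penalty (default floor 0.9, width 0.1 g/L) above
  the 0.6 g/L free-3HPA concentration at which the oxidative-branch
  aldehyde dehydrogenase is inhibited; the smooth form keeps the ODE
  right-hand side Lipschitz, and a hard threshold is available
  (`pdup_inhibition_smooth = FALSE`). The mild floor reflects that
  accumulations of 1–1.7 g/L are observed without collapse of the branch
  rates.
* Redox coupling is enforced structurally (`r2 = r3`) rather than by
  simulating NAD⁺/NADH mass action, for which no pool sizes are
  measurable from broth data. The cofactor carryover from the growth
  phase — the reason early-run apparent rates exceed steady rates — is a
  single pool (`nadh_pool`, default 0.05 mmol/g_CDW) drained into extra
  1,3PDO production at a first-order rate (`nadh_drain_k = 2`/h), so the
  early transient favours the diol and decays within the excluded startup
  window.
* Scavenger batch mode adds fast irreversible 1:1 binding of free 3HPA to
  carbohydrazide (second-order, `k_bind = 1e4` L/mol·h), large enough
  that free 3HPA stays far below both inhibition thresholds while free
  scavenger remains; the complex is exempt from all inhibition terms and
  is tracked in 3HPA mass-equivalents.
* GDH suicide inactivation and its ATP-dependent reactivase cycle are
  **not** simulated — no rate constants are measurable from the data this
  package handles; the toxicity shut-off is the coarse stand-in.

Integration uses `deSolve::lsoda` (stiff-capable) segment by segment over
the piecewise-constant feed profile, with `rtol = 1e-8`,
`atol = 1e-10` mol and a 0.25 h output grid by default. Rate laws clamp
states at zero inside the derivatives, so trajectories cannot run
meaningfully negative; a guard aborts with the failing time if they ever
do. Halving the tolerances changes sampled concentrations by far less than
0.1%. Volume bookkeeping `V(t) = V0 + Σ F_vol·Δt` is exact, and the C3
backbone is conserved to the solver tolerance (≤ 1e-6 relative) at every
sample.

## Calibrated scenarios

[calibrate_scenario()] returns the six study protocols: for each strain a
fed-batch run at pH 7 (1 h batch of 2 g/L glycerol in 1 L with 6 g_CDW,
then 50 g/L glycerol at 12, 31.1 and 50 mL/h × 10 h), a fed-batch run at
pH 5 (12, 19.8, 38.1 mL/h for 11, 10, 10 h), and a 0.5 L batch with
50 g/L glycerol, 50.6 g/L carbohydrazide and 6 g_CDW/L. pH is a label
selecting capacities; there is no mechanistic pH dependence. Note that the
step rates are specified volumetrically: the nominal "1.6 g/h" step is
31.1 mL/h × 50 g/L = 1.555 g/h.

Strain GDH capacities (`vmax_gdh` 17.9 and 36.0 mmol/g_CDW·h for the
wild type and the *pdu*-overexpressing strain) are calibrated so the
scavenger batch converts 50 g/L glycerol in about 6 h and 3 h
respectively. Branch capacities per strain and pH are calibrated so the
simulated analysis-window 3HPA accumulation rate matches the reference
flux table at the highest accumulating step; with mass conservation this
brings uptake and both product rates of the closure-consistent table rows
within ~3% as well. Rows of that table that themselves violate the node
balance (a low-feed uptake above the feed/biomass supply bound; one
high-feed row whose printed products exceed closure by ~8%) cannot be
matched by any mass-conserving simulator; the estimator surfaces closure
residuals instead of forcing agreement.

Under the scavenger, free 3HPA is so low that the branches are nearly
starved, so simulated batch 3HP/1,3PDO byproduct titers undershoot
observed values; batch scenarios are calibrated only for conversion time,
not byproduct formation.

## Flux estimation policy

Apparent rates in the first hours of a resting-cell run are inflated by
the growth-phase cofactor carryover, so fluxes are computed per feeding
step over windows that exclude startup data. The exact excluded span is
ambiguous in general (a "first 10 h" rule overlaps the first feed step),
so the policy is explicit and configurable ([estimation_policy()]):
default `exclude_startup_h = 10` from run start plus `settle_h = 1` after
every feed-rate change. `v4` is always taken from the *measured* 3HPA
accumulation, never from node closure; closure is reported as a
diagnostic residual (≤ 5% of `|v1|` expected on noiseless data), so that
inconsistencies in the data remain visible. Endpoint estimates carry no
per-estimate uncertainty (between-replicate SDs are the natural error
measure, reproduced by [generate_duplicate_pair()]); the regression
estimator's slope standard error is available from the window fit.

## Synthetic data

[generate_run()] emulates HPLC-like sampling of the protocols:
simulator trajectories on a discrete grid, multiplicative Gaussian noise
(default CV 2%, roughly the scale-free relative precision of the assay
chain and of the duplicate-run scatter), a 0.05 g/L detection floor,
clamping at zero, and exact time/volume (controlled variables). Sub-seeds
derive from one master seed by a fixed splitting rule recorded in the
truth sidecar, which also stores the noiseless trajectory, the fluxes
estimated from it, and a node-closed ("balanced") flux set. The noise
model does not emulate chromatogram artefacts, retention-time drift,
species-specific assay biases, or correlated errors between species, so
passing recovery tests demonstrate robustness to unbiased random error
only — not to the systematic errors real assays can carry.
[recover_parameters()] applies noise without the detection floor so its
noiseless limit is exact.

## Problem sizes and verification

The test suite asserts, among others: exact node closure of inferred
fluxes; C3 conservation and exact volume bookkeeping of simulated runs;
the supply bound (steady-step uptake equals feed/biomass until capacity
is exceeded, after which 3HPA accumulates); estimator equivalence on
constant-volume data; and flux recovery at 2% noise across 50 seeded
replicate runs of the engineered-strain pH-7 scenario, where at least 90%
of per-step uptake estimates fall within ±10% of the noiseless truth.
Simulations use the default 0.25 h grid (125 samples per 31 h run), which
keeps the full suite in the seconds range on a single CPU.

One computed quantity deserves a caveat: over the *full* engineered-strain
pH-7 protocol the simulator yields 0.935 mol of products per mol of
glycerol consumed, not ~1.0, because the calibrated final feeding step
accumulates 3HPA at ~10% of uptake for a third of the run. A cumulative
yield of ~1 holds exactly for the steps operated below branch capacity,
and for all C3 products including 3HPA everywhere (conservation). The
split ratio and product molar ratio remain at 1.00 throughout.

## Known limitations

* Resting cells only: no growth, no biomass change, no DHA branch.
* No mechanistic pH dependence, no GDH inactivation/reactivation cycle,
  no intracellular compartmentalization (metabolosome transport is
  absorbed into the lumped rate laws).
* Batch-mode byproduct titers under scavenger are underestimated (see
  above).
* `V(t)` ignores sampling withdrawals and base addition.
* The measurement model is unbiased and uncorrelated by construction.
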
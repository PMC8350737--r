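---
title: "Models and methods behind zymoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zymoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

zymoflux models glucose/xylose co-fermentation to 2,3-butanediol (2,3-BDO)
by a pyruvate-decarboxylase-deficient *Zymomonas mobilis* strain at three
levels: transporter kinetics, pathway thermodynamics/enzyme cost, and
whole-network dynamic flux balance analysis (dFBA). This vignette explains
the models, the tunable parameters, the numerical machinery, and what the
synthetic-data tests do and do not establish.

## Transporter uptake model

Both sugars cross the membrane through the glf facilitator; each acts as a
competitive inhibitor of the other's transport:

$$ v_{glc} = \frac{V_{max,glc}\,[glc]}{K_{m,glc}\left(1 +
   [xyl]/K_{i,xyl}\right) + [glc]}, \qquad
   v_{xyl} = \frac{V_{max,xyl}\,[xyl]}{K_{m,xyl}\left(1 +
   [glc]/K_{i,glc}\right) + [xyl]} $$

with rates in mmol gDCW⁻¹ h⁻¹ and concentrations in mM. Batch depletion
follows $d[glc]/dt = -v_{glc}[X]$ (likewise xylose), where the biomass
$[X](t)$ is *data*, interpolated linearly between measured points — growth
is deliberately not modeled at this layer, which decouples transporter
estimation from any growth assumption.

**Estimation.** `fit_transporter()` minimizes the pooled, unweighted sum of
squared concentration residuals (mM²) of both sugars. Both sugars span
comparable hundreds-of-mM ranges, so no per-channel weighting is applied.
All six constants are optimized in log space; the inhibition constants are
bounded to [1, 10⁴] mM because batch data constrain them only weakly.
Deterministic starts cover three inhibition regimes (strong, moderate,
negligible) since the likelihood has nearly degenerate valleys along the
$K_m(1+[xyl]/K_i)$ direction; optional log-uniform random restarts and a
final refinement pass with a smaller finite-difference step complete the
search. Residuals are computed with a fixed-step classical Runge–Kutta
integration on the observation grid: unlike an adaptive integrator, the
fixed-step solution is a smooth deterministic function of the parameters,
so the Levenberg–Marquardt finite-difference Jacobian is not polluted by
step-size chatter (the public `simulate_uptake()` keeps `deSolve`'s
adaptive `lsoda`).

**Identifiability.** With the default synthetic design (443/245 mM sugars,
65 h, 27 samples, 2% multiplicative noise), $V_{max}$ of both sugars and
$K_{m,xyl}$ are recovered with useful accuracy, but $K_{m,glc}$ is not:
xylose only falls from 245 to roughly 190 mM while glucose is present, so
the data pin the *product* $K_{m,glc}(1 + [xyl]/K_{i,xyl})$ rather than its
factors, and the unidentifiable $K_{i,xyl}$ drags $K_{m,glc}$ with it. On
noise-free data the global optimum is exactly the generating parameters
(the estimator is consistent); under realistic noise the two likelihood
valleys become statistically indistinguishable. Reported inhibition
constants from batch fits should therefore be read as order-of-magnitude
statements, and $K_{m,glc}$ as conditional on the inhibition model — an
experiment varying xylose at fixed glucose would break the degeneracy.

## Synthetic fermentation generator

`generate_fermentation()` emulates the modeled batch: initial glucose and
xylose of 443 and 245 mM, a 65 h horizon, and a *prescribed* logistic
biomass curve (default: inoculum 0.277 gDCW L⁻¹ = OD 0.84 × 0.33, specific
rate 0.20 h⁻¹, plateau 2.5 gDCW L⁻¹ — values chosen once so that glucose
falls below a few mM near 25 h and xylose empties within the batch, the
timeline described for the experiment). 27 equally spaced samples emulate
a realistic HPLC sampling density. Measurement noise is multiplicative,
`value × (1 + cv·ε)` with `ε ~ N(0,1)`, clamped at zero, because
chromatographic error scales with concentration. The sugar ODEs are driven
by the *sampled-then-linearly-interpolated* biomass curve, so the emitted
table is exactly representable by the fitting model — the generator tests
estimator consistency, not interpolation bias. Default inhibition
constants are stand-ins ($K_{i,xyl}$ = 200 mM, $K_{i,glc}$ = 600 mM,
reflecting that glucose's inhibition constant is reported only as much
larger than xylose's). The generator does not attempt HPLC peak artifacts,
OD error structure, or the experiment's two-stage agitation schedule;
passing tests say nothing about those features of real data.

## Pathway thermodynamics (MDF)

Each route is an ordered list of reactions with transformed standard Gibbs
energies ΔG°′ (kJ mol⁻¹; water and protons are absorbed into ΔG°′ and
excluded from the concentration vector) and a relative flux per mol
2,3-BDO. The glucose route carries unit flux everywhere; the xylose route
uses the carbon-balanced split (1.2 through entry, 0.4 through the pentose
rearrangement, 0.8 through the ED reactions, 1.2 through lower glycolysis)
— the unique split turning 1.2 C5 into one C4 diol plus 2 CO₂. Net yields
read directly off the flux-weighted stoichiometry: 1 ATP and 2 CO₂ per
2,3-BDO from glucose; 1.2 ATP, 0.2 NADH and 0.8 NADPH from xylose.

The max–min driving force is the LP

$$ \max_{x,\,B} B \quad \text{s.t.} \quad -(\Delta G^{\circ\prime}_j +
   RT\,S_j^\top x) \ge B,\; \ln c_{lb} \le x \le \ln c_{ub}, $$

over log molar concentrations, bounds 1 µM–10 mM for intracellular
species, extracellular sugars pinned at their (measured) values, transport
assigned ΔG°′ = 0. Temperature defaults to 298.15 K for consistency with
standard-state Gibbs energy sources, although the fermentation runs at
30 °C; it is configurable. Because the maximin optimum generally leaves
slack concentrations underdetermined, a secondary LP minimizes the total
pathway ΔG′ at the fixed optimal $B$, making the reported concentration
vector and cumulative profile well defined. The cumulative profile is the
unweighted running sum of per-reaction ΔG′ in pathway order. Bottlenecks
are reactions with ΔG′ > 0 at a uniform 1 mM reference. Time-course scans
re-pin the substrate at each sampled concentration, clipped below at
10⁻³ mM to keep logarithms finite near depletion. Cofactor-ratio scans add
the equality $x_{num} - x_{den} = \ln r$ and report the re-optimized
totals; for the (net ATP-producing) sugar routes the total driving force
strengthens as ATP/ADP falls.

## Enzyme protein cost

The enzyme mass demanded by reaction $j$ at flux $v_j$ (mol s⁻¹)
factorizes as

$$ E_j = \frac{MW_j\, v_j}{k_{cat,j}\; \eta_{rev}\; \eta_{sat}}, \qquad
   \eta_{rev} = 1 - e^{\Delta G'_j / RT}, $$

with the common modular rate law saturation term
$\eta_{sat} = \prod_S (s/K_m)^{|\nu|} \big/ \left[\prod_S (1+s/K_m)^{|\nu|}
+ \prod_P (1+p/K_m)^{|\nu|} - 1\right]$. The modular rate law admits several
equivalent writings; this factorized form is the standard
enzyme-cost-minimization reading and is the one implemented here. Reverse rates obey the Haldane relationship
$k_{cat}^- = k_{cat}^+ \prod_P K_m^{|\nu|} / (K_{eq} \prod_S K_m^{|\nu|})$
with $K_{eq} = e^{-\Delta G^{\circ\prime}/RT}$. Irreversible steps
(transport, both decarboxylations by default — large negative ΔG°′ and gas
release) take $\eta_{rev} = 1$ and exclude product terms from saturation;
species without a Michaelis constant (e.g. CO₂) do not enter saturation.
Demand can never fall below $MW\,v/k_{cat}$.

Total cost per unit pathway flux (1 mol 2,3-BDO s⁻¹, so $v_j$ equals the
relative flux) is minimized over the same bounded log-concentration space
as the MDF, subject to ΔG′ ≤ −10⁻³ kJ mol⁻¹ for every reversible reaction.
The solver is SLSQP from the MDF-optimal vector (feasible whenever
MDF > 0) plus seeded, feasibility-filtered jittered restarts; as a guard,
the returned solution is never worse than the cost at the MDF optimum
itself.
Time-course scans warm-start each point from the previous optimum.
Infeasible timepoints are flagged, never dropped.

## Core network and dynamic FBA

The shipped network (39 reactions, 36 metabolites) reduces the strain's
central metabolism to: glucose/xylose entry, the ED route, the pentose
phosphate rearrangement, lower glycolysis, the acetolactate→acetoin→2,3-BDO
branch (butanediol dehydrogenase reversible, so the diol can be re-oxidized
when re-uptake is allowed), glycerol formation as the NADPH sink, NADH and
NADPH oxidases as electron sinks, a lumped biomass reaction, non-growth
maintenance (lower bound zero), and the knocked-out pyruvate
decarboxylase/ethanol branch (bounds (0,0)). Respiration is ATP-uncoupled
by default (`po_ratio = 0`), consistent with this organism's famously low,
uncoupled growth yields; the biomass reaction drains ~40 mmol C gDCW⁻¹ of
precursors plus 100 mmol ATP gDCW⁻¹ — the ATP coefficient lumps
polymerization and growth-associated maintenance and was calibrated once so
the default batch depletes glucose near 25 h and both sugars within 65 h.
The OD→biomass factor (0.33 gDCW L⁻¹ per OD unit) is a configurable
default; no published value exists for this strain. This network is *not*
the 79-reaction supplementary reconstruction; exact reaction/metabolite
counts are only asserted against that file, which `build_core_network()`
can load from SBML L3/FBC or a tabular reaction list.

Each dFBA step solves a lexicographic sequence — max biomass, max 2,3-BDO
export, max acetoin, max glycerol, then min glucose, xylose and oxygen
uptake — fixing each optimum within 10⁻⁶ relative before the next. 2,3-BDO
precedes acetoin because it is the target molecule and acetoin accumulates
only after glucose exhaustion in the modeled experiment; glycerol is placed
last among products (no unique ordering is dictated by the model; the
stage list is configurable). Uptake bounds come from the
kinetic laws at the current state; products may always be secreted;
acetoin/2,3-BDO re-uptake is capped by Michaelis–Menten kinetics (Vmax
10 mmol gDCW⁻¹ h⁻¹, Km 5 mM), oxygen by Vmax 15 mmol gDCW⁻¹ h⁻¹ with
Km 1.24 µM, and gas transfer by kLa (default 30 h⁻¹, the modeled value at
300 rpm; a single constant even though the experiment ramped agitation)
toward saturation 0.21 mM.

**Integration.** The static optimization approach freezes fluxes over each
step (default dt = 0.1 h): biomass grows exponentially at the solved rate,
sugar/product balances use the step-averaged biomass, and dissolved oxygen
— whose Michaelis constant sits three orders of magnitude below the mM
scale, making the ODE stiff — follows the *exact* solution of its linear
within-step ODE, which prevents the negative overshoot an explicit Euler
update produces at this step size. Concentrations clamp at zero.
Infeasible steps advance the state with zero biological flux (abiotic
oxygen transfer still applies) and are flagged. Halving dt moves the final
titer by well under 1%.

**Expected deviations.** Growth-maximizing FBA with a coarse biomass
reaction overpredicts biomass accumulation — the validation account of
this model family reports the same bias — and the simulated 2,3-BDO titer
is correspondingly optimistic, since unmodeled by-products and maintenance
are funneled into product and biomass. Scan *rankings* (which ratio or
aeration is best) are the robust outputs, not absolute titers.

## Condition scans

`sugar_ratio_scan()` varies the molar glucose:xylose ratio (0.5–4; the
1:2 condition is r = 0.5) holding total substrate carbon at
6·443 + 5·245 = 3883 mM C, solving `6·glc + 5·xyl = C, glc = r·xyl`
exactly; "ratio" is molar by default (the validation medium is ≈1.8 molar),
with the carbon-mole reading available by converting externally.
`kla_scan()` varies the transfer coefficient and reports both maximum
productivity `max_t [BDO](t)/t` (earliest time on ties) and final titer,
because the two objectives disagree about aeration: faster oxygen supply
accelerates substrate turnover and productivity, while titer favors
moderate aeration. Scans are deterministic and embarrassingly parallel.

## Parameter provenance

The pathway files ship topology, relative fluxes, reversibility and the
transport ΔG°′ = 0 only. Published thermodynamic and kinetic constants for
the enzymes live in the original supplementary data sheet (standard Gibbs
energies from eQuilibrator; Michaelis constants, turnover numbers and
molecular weights from BRENDA, geometric-mean-merged, heterologous enzymes
taken from their host species); that sheet is not redistributable here.
`load_parameter_table()` reads any table in the documented TSV/CSV dialect
and `merge_parameters()` overlays it, reporting remaining gaps as a
checklist. `inst/extdata/params_synthetic.tsv` is a synthetic stand-in
with field-plausible magnitudes, constructed so the qualitative structure
(three glucose-route bottlenecks, two additional xylose bottlenecks,
acetolactate synthase dominating protein cost, glucose cheaper than
xylose) emerges from the same machinery; its absolute MDF and cost values
are not the published ones and are not asserted anywhere.

## Numerical choices at a glance

- **Linear programs** (MDF, FBA): solved by a proximal-point iteration on
  quadprog's dual QP method — repeatedly minimizing
  $(\varepsilon/2)\lVert x - x_k\rVert^2 - c^\top x$ over the constraint
  set. For polyhedral sets this terminates at an exact LP optimum (the
  fixpoint condition is exactly LP optimality) and, as a side effect,
  returns the least-norm point of the optimal face, so flux vectors carry
  no free internal cycles. Redundant equality rows (paired conserved
  moieties such as ATP/ADP) are removed by QR factorization first. All
  variables are box-bounded, so no LP is unbounded.
- **Tie-breaks**: MDF concentrations by secondary total-ΔG′ minimization;
  lexicographic FBA fixes each stage within 10⁻⁶ relative.
- **Floors and guards**: substrate pins clipped at 10⁻³ mM in time-course
  scans; ΔG′ ≤ −10⁻³ kJ mol⁻¹ strict-feasibility margin in cost
  minimization; concentrations clamped at zero in all integrators.
- **Degenerate inputs**: pathways failing the steady-state balance are
  rejected naming the intermediate; zero-variance observations make R²
  `NA` with a warning; infeasible MDF pins and cost problems raise typed
  errors naming the tight reaction.
- **Problem sizes** (defaults used by the test suite): 27-sample courses,
  20-seed recovery studies, 3-reaction toy pathways against grid oracles
  (400-point grids), 65 h batches at dt = 0.1 h with a dt = 0.05 h
  convergence check.

## Known limitations

- $K_{i}$ values (and through them $K_{m,glc}$) are weakly identified from
  single batch co-fermentation data; see the identifiability note above.
- The thermodynamic layer consumes ΔG°′ as given: no pH/ionic-strength
  transformation, no uncertainty propagation.
- The enzyme-cost objective is near-convex in log concentrations but not
  certified convex; multi-start SLSQP is a heuristic, albeit one whose
  optimum is grid-verified on small instances in the test suite.
- The shipped core network omits the TCA remnant and lumped by-products
  (lactate, acetate, succinate); carbon that would leak there inflates
  biomass and 2,3-BDO predictions.
- dFBA assumes intracellular pseudo-steady state per step; no regulation,
  no lag phases, no product inhibition of growth.
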
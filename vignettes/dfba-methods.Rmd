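---
title: "Dynamic flux balance analysis of glycerol fermentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic flux balance analysis of glycerol fermentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `pdodfba`, the
assumptions behind them, the construction and calibration of the bundled
reduced network, the numerical machinery, and the limitations a user
should keep in mind when transferring conclusions to real fermentations.

## 1. The instantaneous flux problem

Anaerobic growth of *Clostridium butyricum* on glycerol is represented by
a constraint-based model: fluxes `v` (mmol/gDW/h) satisfy the
steady-state balance `S v = 0` of the intracellular metabolites and box
bounds, and the realized distribution maximizes

$$Z \;=\; \frac{\mu}{\,w \sum_j v_j^2 + (1-w)\, v_{\mathrm{ATPprod}}^2\,}$$

the growth rate per squared flux, a member of the "efficient growth"
objective family. The weight `w` encodes the physiological regime:

* **Glycerol limitation** (`< 15 g/L`): `w = 1`. The denominator is the
  total squared flux, so the cell grows as efficiently as its enzyme
  budget allows — the classic parsimonious-growth phenotype with the
  high-ATP acidogenic routes favored.
* **Glycerol excess** (`>= 15 g/L`): `w = 0.04`. Almost all the weight
  moves onto the squared flux of the regulable ATP-forming steps (the
  acetate and butyrate kinases), reproducing the overflow phenotype:
  submaximal ATP generation, more carbon pushed through the reductive
  branch, higher PDO yield.

The concentration exactly at the switch belongs to the excess regime (the
phenotype change is triggered by *falling below* the threshold), and the
death constant switches at the same boundary; no hysteresis is applied.

Two renderings of the objective are conceivable (a ratio or a product of
numerator and denominator); the ratio is the default because only it
reproduces the regime phenomenology above (the product form rewards
maximal flux magnitudes in both regimes), but `objective_spec(form =
"product")` exposes the literal product reading.

**Why uptake is an equality.** The glycerol uptake flux is *pinned* to
the kinetic value (Ghose–Tyagi, below) rather than merely bounded by it.
With a free uptake bound and no maintenance demand the ratio objective is
degenerate: scaling any growing flux vector down by `λ` multiplies the
numerator by `λ` and the denominator by `λ²`, so `Z → ∞` as `v → 0` and
the optimizer would starve the cell. Pinning uptake at the kinetic rate
— the standard DFBA treatment of substrate kinetics — removes the
degeneracy. A consequence is that the textbook monotonicity "relaxing
the uptake bound cannot decrease the optimum" holds in the only form
that is meaningful here: the growth rate is non-decreasing in the
prescribed uptake, and relaxing any genuine inequality (for instance the
acetate ceiling) never decreases `Z`; both are property-tested.

**Disposal capacity.** At some parameter combinations the kinetic uptake
exceeds what the network can metabolize (the acyl-CoA disposal routes
and the NADH sinks saturate). The cell then consumes at the largest
processable rate: the engine computes this capacity by an exact
max-uptake linear program with the acetate ceiling made self-consistent
by fixed-point iteration, verifies it, and caches it per simulation.

## 2. The bundled reduced network

The bundled network lumps anaerobic glycerol metabolism into 23
reactions over 17 metabolites: a reductive branch (glycerol + NADH →
PDO), an oxidative branch (glycerol → pyruvate, net +1 ATP, +2 NADH),
pyruvate:ferredoxin oxidoreductase, hydrogenase and NADH:ferredoxin
oxidoreductase, acetate (+1 ATP), butyrate (+1 ATP per two acetyl-CoA,
−2 NADH), lactate, ethanol and butanol branches, a maintenance ATPase,
and a lumped biomass reaction. CoA is a balanced carrier without carbon
in the bookkeeping; every internal reaction conserves carbon exactly,
which makes the culture-level carbon balance checkable to numerical
precision.

Three construction choices deserve explanation:

* **Minor-route capacities.** Lactate, ethanol and butanol are trace
  products of *C. butyricum* glycerol fermentations. With all routes
  unbounded, the quadratic objective spreads overflow carbon across a
  near-degenerate ridge of byproduct routes and predicts g/L-scale
  lactate, which is unphysiological. Their lumped capacities are
  therefore bounded at the observed secretion scale (0.5, 1.0 and 0.5
  mmol/gDW/h).
* **Butyrate capacity.** Enzyme-activity measurements show the
  butyrate-forming branch (thiolase) does not expand with glycerol
  uptake while acetate kinase does. The butyrate kinase route is capped
  at 3 mmol/gDW/h; without this cap the objective always prefers
  butyrate (half the penalized kinase flux per acetyl-CoA) and the
  acetate ceiling could never bind — contradicting the observed
  acetate-over-butyrate phenotype at excess.
* **`v_ATPprod`.** The ATP-production flux in the objective is the sum
  of the acid-forming kinase fluxes (ACK, BUK). The ATP formed inside
  the lumped glycolytic reaction is stoichiometrically tied to carbon
  oxidation and not independently regulable; counting it suppresses
  acetate secretion entirely at excess, again contradicting the
  phenotype the objective is meant to capture.

**Biomass composition.** The lumped biomass reaction is parameterized by
44 precursor coefficients (20 amino acids, 8 nucleotides, 7 fatty acids,
3 polar lipids, 6 cofactors) and 8 macromolecule mass fractions (protein
0.52, RNA 0.16, DNA 0.03, lipid 0.076, teichoic acid 0.03, peptidoglycan
0.08, carbohydrate 0.09, trace pool 0.014). Each precursor carries a
molar mass, a carbon count split exactly into pyruvate and acetyl-CoA
units, and lumped ATP/NADH synthesis costs; the aggregate drains define
the biomass column of `S`. At the default composition the biomass
molecular weight is exactly 1 g/mmol (the usual FBA normalization).
Sampled macromolecule fractions are renormalized to sum to one (they are
mass fractions of one gram of cells); precursor coefficients perturb the
within-class make-up freely, which is why a 30 % composition RSD maps to
a few-percent dispersion of the biomass molecular weight — the
diagnostic reported by `composition_rsd_sweep()`.

**Calibration.** The growth-associated ATP demand (GAM, default 85 mmol
ATP/gDW on top of ~29 mmol/gDW of synthesis costs) is the one free
constant of the biomass reaction. It was set, once, so that the model
reproduces the benchmark batch culture reported for this organism — a
46 g/L, 0.12 g/L-inoculum batch finishing near 24 h at ~1 g/L·h
productivity and ~23 g/L PDO. This is ordinary surrogate-model
calibration against published phenotypes, not a fit to any dataset
shipped with the package.

## 3. Kinetic constraints

| parameter | meaning | default | units |
|---|---|---|---|
| `vmax_gly` | maximal glycerol uptake | 174.86 | mmol/gDW/h |
| `ks_gly` | uptake affinity constant | 482.1 | mM |
| `ki_gly` | uptake inhibition constant | 755.4 | mM |
| `v0_aa` | basal acetate ceiling | 0.1578 | mmol/gDW/h |
| `vinf_aa` | maximal acetate ceiling | 11.50 | mmol/gDW/h |
| `R_aa` | ceiling accumulation rate | 0.0859 | g·h/mmol |
| `kd_lim` | death constant, limitation | 0.0350 | 1/h |
| `kd_exc` | death constant, excess | 0.0105 | 1/h |
| `switch_gly` | regime threshold | 15 | g/L |

Glycerol enters the uptake law in mM (conversion 92.09 g/mol,
centralized in `gl_to_mM()`); PDO is reported with 76.09 g/mol. The
uptake law is zero at 0 and at `ki_gly`, unimodal with its maximum at
`ks·(sqrt(1 + ki/ks) − 1) ≈ 290 mM`; the acetate ceiling is strictly
increasing from `v0_aa` toward `vinf_aa`. Non-growth-associated
maintenance defaults to zero (configurable via `reduced_network(ngam=)`);
its omission is the known cause of optimistic predictions at very low
glycerol.

## 4. The three solution strategies

* **SOA** (`approach = "soa"`): explicit forward Euler with `G` steps;
  the flux problem is re-optimized each step, warm-started from the
  previous step (the warm flux vector is rescaled to the new uptake,
  which preserves `S v = 0` exactly). If a step would drive glycerol
  negative, the uptake is rescaled to consume exactly the remainder.
* **DA** (`approach = "da"`, default): `deSolve::lsodar` (adaptive,
  rtol 1e-6, atol 1e-8) with the optimization embedded in the
  right-hand side; a root function stops the integration exactly at the
  15 g/L regime switch (and at the reactor's maximal volume in
  fed-batch) so each segment has a fixed objective.
* **DOA** (`approach = "doa"`): orthogonal collocation over the whole
  horizon on the roots of a degree-6 orthogonal polynomial
  (Gauss–Legendre by default; both Chebyshev families, Laguerre and
  Hermite are available and give indistinguishable trajectories). The
  states are degree-6 Lagrange polynomials through the initial point and
  the nodes; the collocation NLP is solved in reduced space: node states
  are the unknowns, each node's flux subproblem is solved to global
  optimality inside the residual evaluation, and a damped Newton
  iteration (numerical Jacobian, ~60 unknowns) drives the mass-balance
  residuals to ~1e-12; the attained objective (the sum of `Z` over the
  reporting grid) is recorded in the diagnostics. DOA refuses horizons
  that cross the regime switch — a single objective must hold over the
  whole collocation polynomial — with an explanatory error.

Fed-batch operation integrates amounts (`V·z`, `V·X`, `V`) with feed
`F = α` (constant) or `F = β·v_{H+}·X·V` (coupled to pH control through
the proton-secretion flux, taken as the summed acetate + butyrate +
lactate secretion since each acid leaves with one proton). Feeding stops
at `V_max`; the bundled reactor is 1 L initial, 1.5 L maximal. The feed
carries glycerol only (nitrogen and phosphorus are assumed non-limiting)
at `S_F = 10 × (mass %)` g/L, a unit-density approximation adequate for
the ≤30 % feeds scanned.

## 5. Sensitivity analyses and the population balance model

The 60 input parameters are the 44 precursor coefficients, 8
macromolecule fractions, 3 acetate-ceiling constants, 2 death constants
and 3 uptake constants. Ensembles draw each parameter from a normal
distribution with 30 % relative standard deviation (20 % for the three
uptake constants), resampling non-positive values.

**MPSA** scores every draw against a reference culture (by default a
synthetic six-point observation table of the bundled glycerol-excess
batch) through the per-observation mean squared error of the PDO profile
and the squared errors of productivity and yield; the error-propagation
thresholds are (6 g/L)², (0.057 g/L·h)² and (0.052 mol/mol)². The
squared-error statistic divides by the number of points so those
per-observation thresholds apply directly; `mse_profile(mean = FALSE)`
restores the raw sum. A draw is *unacceptable* when its error strictly
exceeds the threshold, and each parameter's influence is the
Kolmogorov–Smirnov distance between its acceptable- and
unacceptable-class distributions, compared against `1.36/sqrt(K)`.
Classification is per output; parameters with an empty class are
reported as not classifiable.

**PRCC** rank-transforms parameters and outputs and computes partial
correlations through the precision matrix (controlling each parameter
for the other 59); a `"pearson"` mode skips the rank transform. Only the
static outputs (productivity, yield) are analyzed. On the full pipeline
the three uptake constants dominate, with `vmax_gly` and `ki_gly`
positive and `ks_gly` negative — the expected directions for a
saturating, substrate-inhibited uptake.

**PBM.** Cell-to-cell variability is modeled numerically: each "cell
line" is a whole-culture simulation with one parameter draw from the
chosen group (precursors, macromolecules, death constants, acetate
kinetics, or all 57 — uptake kinetics are population-level properties
and excluded). Draws are derived from `(seed, cell index)`, so ensembles
are nested and bit-reproducible, and the dispersion profile RSD(t) of
PDO is reported. The reference culture runs to 28 h so that every cell
line finishes its fermentation; otherwise the end-of-culture dispersion
would conflate timing truncation with the yield variability the PBM is
meant to quantify.

## 6. Design-space scans

The batch factorial covers 15 inoculum levels (0.01–0.15 g/L; the
exponential-phase inoculum constraint caps the practical value at 0.12)
by 13 glycerol levels (5–65 g/L). Fed-batch grids cover feed glycerol
contents of 5–30 mass % (the range of crude-glycerol feeds used in
fed-batch practice) against log-spaced feeding constants chosen to
bracket under- and over-feeding (`α` in 0.003–0.03 L/h, `β` in
1e-4–3e-3 L/mmol). Outcomes are classified as infeasible (no
production, or overfeeding in constant mode), unconsumed-glycerol
(pH-coupled mode, residual > 5 g/L at the end), suboptimal, or optimal;
the pH-coupled optimum must additionally reach a mass conversion of at
least 45 % of the *fed* glycerol (the conservative denominator; the
consumed-basis conversion is also reported).

## 7. Numerical choices

* Flux optimization: Dinkelbach iteration on the ratio objective;
  subproblems are strictly convex QPs solved by a primal active-set
  method with exact KKT solves; first feasible points from an ADMM
  splitting with residual-balanced penalty and an alternating-projection
  fast path. Convergence: 1e-8 relative on the Dinkelbach value,
  constraint residuals below 1e-6 (typically 1e-10). Multistart (three
  deterministic seeds) is retained and tested to agree — the subproblem
  convexity makes every start reach the global optimum.
* Degenerate inputs: a culture with zero uptake returns the zero-growth
  flux state with `Z = 0`; zero biomass freezes the medium; all-zero
  compositions are flagged.
* Ties: within the quadratic objective ties are broken by the
  minimum-norm character of the active-set solution; no randomness is
  involved anywhere in the deterministic pipeline.
* Problem sizes: the default discretizations are `G = 100` (SOA/DA
  grids), 6 collocation points (DOA), `G = 240` for the 72 h fed-batch
  scans, and `G = 36` (with 24 usable for convergence studies) for PBM
  ensembles; these keep a full sensitivity-plus-PBM analysis on one CPU
  in minutes while staying within ~1 % of finer-grid results for the
  quantities reported.

## 8. What the synthetic data do and do not show

`generate_batch_observations()` samples the bundled scenarios with
multiplicative 5 % noise plus a 0.05 g/L additive floor (chromatography
detection limits), truncated at zero; sampling is regular by default
with an "irregular" preset that samples more densely early. Parameter
recovery tests (noise-free recovery of the uptake and ceiling constants
to 0.1 %, unbiasedness under noise) validate the *fitting machinery*,
and the pipeline tests validate internal consistency of the simulator.
They do not validate the biology: the synthetic tables inherit every
assumption of the generating model (no pH or product inhibition, lumped
stoichiometry, regime switching at exactly 15 g/L), so passing tests
demonstrate correct computation, not predictive accuracy on real
fermentations.

## 9. Known limitations

* The reduced network is a surrogate for a genome-scale metabolism. Its
  acetate ceiling is the binding acyl-CoA disposal route at excess, so
  perturbations of the ceiling parameters transmit almost one-to-one
  into the PDO yield; a genome-scale model buffers them through
  alternative routes, and the surrogate therefore overstates the PDO
  dispersion caused by acetate-kinetics variability (about 4 % here
  versus the ~2 % scale expected of the full metabolism).
* There is no product, osmotic or pH inhibition of growth. In long
  fed-batch simulations biomass keeps compounding, so high-titer
  cultures finish faster than real ones; predicted titers are
  reasonable, predicted fed-batch *productivities* are optimistic.
* Maintenance (NGAM) defaults to zero, which overestimates growth and
  PDO at very low glycerol; this is visible below ~5 g/L.
* The pH-coupled feed law is the printed proportionality only; no buffer
  chemistry or base-addition balance is modeled.
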
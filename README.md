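# pdodfba

Dynamic flux balance analysis (DFBA) of 1,3-propanediol (PDO) production
from glycerol by *Clostridium butyricum*.

Glycerol — the main by-product of biodiesel manufacture — is fermented
anaerobically by *C. butyricum* through two coupled branches: a reductive
branch that converts glycerol and one NADH into PDO, and an oxidative
branch that runs glycerol through pyruvate and acetyl-CoA into acetate,
butyrate and minor acids, generating the ATP and NADH that growth and the
reductive branch consume. How the carbon splits between the branches —
and therefore the PDO titer, yield and productivity of a culture — is an
allocation problem that this package solves dynamically: an instantaneous
constraint-based flux optimization embedded in the extracellular mass
balances of a batch or fed-batch reactor.

## The model

At every instant the intracellular flux distribution `v` solves

```
max  Z = mu / ( w * Σ_j v_j²  +  (1 − w) * v_ATPprod² )
s.t. S v = 0,   v_min ≤ v ≤ v_max
```

where `mu` is the growth rate (the biomass reaction flux), `S` the
stoichiometric matrix of the bundled reduced network of anaerobic glycerol
metabolism, and `v_ATPprod` the summed flux of the acid-forming kinases
(the regulable substrate-level phosphorylation steps). The weight `w`
switches with the extracellular glycerol concentration: `w = 1` at
glycerol limitation (below 15 g/L) and `w = 0.04` at glycerol excess.
The numerator is linear and the denominator a positive-definite quadratic,
so the optimum is found globally by Dinkelbach's parametric algorithm over
convex quadratic subproblems (implemented in C++).

Three kinetic constraints couple the flux problem to the culture state:

* glycerol uptake follows Ghose–Tyagi substrate-inhibition kinetics,
  `v_gly = vmax·G/(ks+G)·(1−G/ki)` with `vmax = 174.86 mmol/gDW/h`,
  `ks = 482.1 mM`, `ki = 755.4 mM`;
* acetate secretion is capped by a logistic ceiling rising from
  0.1578 to 11.50 mmol/gDW/h with the uptake flux (rate 0.0859 g·h/mmol);
* viable biomass dies at `kd = 0.0350 h⁻¹` under limitation and
  `0.0105 h⁻¹` under excess.

The extracellular balances `dz_i/dt = v_i·X·MW_i` (batch) or
`d(Vz)/dt = F·S_F + v·MW·VX` (fed-batch, Eq-style with feed `F`) are
integrated by three interchangeable strategies: **SOA** (explicit stepping
with per-step optimization), **DA** (adaptive integration with the
optimization embedded in the right-hand side), and **DOA** (orthogonal
collocation on six Gauss–Legendre points over the whole horizon).

On top of the simulator the package provides global sensitivity analysis
of the 60 input parameters (MPSA with Kolmogorov–Smirnov classification,
and partial rank correlation coefficients), a Monte-Carlo population
balance model of cell-to-cell variability, factorial scans of batch and
fed-batch culture designs, and generators plus fitting routines for
pseudo-experimental fermentation data.

## Worked example

```r
library(pdodfba)

net  <- reduced_network()                    # bundled C. butyricum network
spec <- dfba_spec(network = net, glycerol0 = 46, X0 = 0.12,
                  tf = 40, approach = "da")  # the scan-optimal batch
traj <- dfba(spec)
summary(traj)
```

```
DFBA DA simulation, batch culture
  final PDO           22.55 g/L
  Q_PDO               0.924 g/L/h  (culture time 24.4 h)
  Y_PDO/S             0.593 mol/mol (0.490 g/g)
  residual glycerol    0.00 g/L; final biomass 1.13 g/L
```

A culture started at 46 g/L glycerol with a 0.12 g/L exponential-phase
inoculum exhausts its substrate in about 24 h, producing 22.6 g/L PDO at
a volumetric productivity of 0.92 g/L·h and a molar yield of 0.59 mol PDO
per mol glycerol — the excess-regime phenotype (high reductive-branch
allocation, acetate at its allosteric ceiling) followed by the switch to
the limitation objective once glycerol falls below 15 g/L.

The instantaneous phenotype at any glycerol level:

```r
flux_state_at(net, 30)   # 30 g/L: excess regime, w = 0.04
```

```
Flux state (w = 0.04, status optimal): mu = 0.1850 1/h, Z = 0.0007453
Nonzero exchange fluxes (mmol/gDW/h):
   EX_glyc     EX_pdo      EX_ac     EX_but  ...
  -40.1031    25.4719     3.4917     3.0000  ...
```

Acetate secretion (3.49) exceeds butyrate secretion (3.00) at glycerol
excess, with the PDO flux taking 64 % of the consumed carbon.

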
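---
title: "Methods: pharmacokinetically driven perturbation of metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacokinetically driven perturbation of metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug detoxification competes with the endogenous metabolism for cofactors
and energy: every mole of drug that is acetylated consumes acetyl-CoA,
every oxidation consumes O2 (and, for CYP-type reactions, NADPH), every
glycine conjugation drains the mitochondrial glycine pool. `dmoma`
quantifies the whole-network consequences of that competition for an
organ — prototypically the liver under isoniazid exposure — by coupling
two model scales:

* a **compartmental pharmacokinetic (PK) model** that produces
  time-resolved intracellular xenobiotic reaction rates
  (µmol·liver⁻¹·min⁻¹), and
* an **organ-specific constraint-based metabolic network** (stoichiometric
  matrix $S$, flux bounds, gene–protein–reaction rules) describing the
  endogenous biochemistry.

The two scales share exactly one interface: the xenobiotic reactions.
Because the PK side balances the drug species themselves, the network only
carries the *cofactor shadow* of each xenobiotic reaction (acetylation:
acetyl-CoA → CoA; hydrolysis: H₂O; oxidation: O₂ (+NADPH → NADP⁺);
glycine conjugation: glycine; and so on, each at its subcellular
location). This cofactor-only splicing is deliberately conservative: all
xenobiotic reactions enter with bounds $[0, 0]$, so the extended network
is flux-equivalent to the base network until the coupling opens them.

## Dynamic minimization of metabolic adjustment

Cells buffer sudden perturbations by *minimal* rearrangement of their flux
state — metabolic rates adjust far faster than expression can. The engine
therefore solves, at every timepoint $i$ of the PK grid, the strictly
convex quadratic program

$$\min_{v_i} \; (v_i - v_\mathrm{ref})^\top (v_i - v_\mathrm{ref})
\quad \text{s.t.} \quad S v_i = 0,\;\; lb \le v_i \le ub,\;\;
v_\mathrm{xeno} = v_\mathrm{PK}(t_i),$$

i.e. the flux distribution closest (Euclidean) to the unperturbed
reference $v_\mathrm{ref}$ among all steady states that exactly honor the
pinned xenobiotic rates. Each step references the *original*
$v_\mathrm{ref}$, not the previous column: the perturbed cell keeps
pulling back toward its evolved homeostatic state, and the run is
trivially parallel over timepoints. (A chained mode — reference = previous
column — exists for exploration but is off by default and excluded from
all quantitative checks.) Strict convexity makes each column unique, so
identical consecutive rate vectors can reuse the previous solution
exactly, and an all-zero rate vector returns $v_\mathrm{ref}$ itself
without invoking the solver (it is feasible with objective 0).

Stacking the columns gives the flux matrix $v_{it}$, from which all
response metrics derive:

* differential fluxes $\Delta v_{it} = v_{it} - v_\mathrm{ref}$;
* integrated perturbations $P_\mathrm{rxn} = \int_0^t |\Delta v_i|\,dt$
  per reaction, $P_\mathrm{ex}$ per exchange (µmol of exchanged
  metabolite), and $P_\mathrm{PBPK}$ summed over the xenobiotic drivers;
* the significance rule $P_\mathrm{rxn} > \varepsilon t$ (strict), with
  $\varepsilon = 10^{-5}$ µmol·liver⁻¹·min⁻¹ the minimal flux threshold;
* pathway perturbations $P_\mathrm{MP} = \sum_{\mathrm{rxn} \in
  \mathrm{MP,\,significant}} P_\mathrm{rxn}$ over a reaction → pathway
  clustering;
* attenuation curves $AT_\mathrm{MP}(t) = \sum_{j \le t}
  P_{\mathrm{MP},j} / P_\mathrm{MP}$, non-decreasing and ending at 1;
* pathway scores $PS = P_\mathrm{MP} / P_\mathrm{PBPK}$, with 0 =
  independence, $(0,1)$ = partial perturbation, $>1$ = aggravation;
* signed exometabolome pool changes $\int \Delta v_\mathrm{ex}\,dt$.

**Integration rule.** All integrals are left-rectangle sums with the
coupling step $dt$: the QP yields piecewise-constant fluxes per step, so
the rectangle sum *is* the exact integral of the simulated trajectory.
The final grid point closes the last interval and contributes no
rectangle. The same discretization enters the significance threshold
($t$ = grid span) and the attenuation numerator; with the global
significance mask used for the per-step pathway perturbations, the
attenuation endpoint equals the pathway total identically.

**Sign conventions.** Internally a positive exchange flux secretes the
metabolite (the exchange column has a single −1 entry). Report layers
also provide the organ-centric uptake-positive convention
(`hepatic_utilization = -pool_change`). The magnitude integral
$P_\mathrm{ex}$ uses $|\Delta v|$; the increased/decreased classification
of exometabolome pools uses the *signed* integral — the magnitude version
alone cannot give a direction, so both are computed.

## Reference-state construction

The unperturbed reference is built in four stages:

1. **Physiological exchange bounds** (fasted state): every exchange is
   closed, then the utilization table opens the physiological ones —
   uptake of the gluconeogenic substrate, oxygen, glycine, water;
   secretion of glucose and CO₂ (secretion-only: $lb = 0$; uptake-only:
   $ub = 0$).
2. **Expression scores**: gene intensities normalized to their maximum,
   propagated through GPR rules with AND → min, OR → max; genes missing
   from the profile drop out of the min/max; rules whose genes are all
   unknown — and reactions without a rule — stay unscored. The **active**
   set is all reactions scoring at or above the 75th percentile of the
   *non-zero* score distribution, the **inactive** set those at or below
   the 25th percentile plus all zero-scored reactions. Percentiles use
   linear interpolation on the sorted score vector (R's default type-7
   quantile) — percentile conventions differ between toolkits, so the
   choice is fixed and documented here. Coinciding thresholds (degenerate
   score distributions) break ties toward the active set, with a warning.
3. **iMAT context extraction**: maximize the number of active reactions
   carrying $|v| \ge \varepsilon$ plus inactive reactions with $|v| \le
   \varepsilon$ (one ε for both sides), subject to steady state, bounds,
   and a minimal biomass flux of $10^{-4}$ µmol·liver⁻¹·min⁻¹. The
   mixed-integer program uses the standard big-M indicator constraints
   and is solved by a deterministic branch-and-bound (most-fractional
   branching, 1-branch first) over an LP relaxation, with a tiny
   index-decreasing weight on the binaries so the optimum is unique and
   reproducible run-to-run. Among optimal activity patterns, the reported
   flux vector is the one of minimal total $\sum_r |v_r|$ realizing the
   pattern — iMAT optima are massively degenerate, and this secondary LP
   pins down a parsimonious, deterministic representative. A reaction is
   pruned from the context network only if it carries $|v| < \varepsilon$
   in the solution **and** flux variability analysis proves it can never
   reach $\varepsilon$ — solution-zero alone is not evidence, because of
   alternative optima. The variability check runs with the xenobiotic
   reactions *opened*: machinery whose only client is the (currently
   closed) drug metabolism — e.g. the mitochondrial glycine transporter
   feeding glycine conjugation — must survive extraction, or the coupling
   would hit an artificially pruned wall at the first nonzero rate.
   Biomass and xenobiotic reactions are never pruned.
4. **Intracellular flux minimization**: minimize $\sum_j |v_j|$ over
   intracellular reactions, holding every exchange flux exactly at its
   iMAT value and the direction of every reaction with $|v| \ge
   \varepsilon$. This realizes the assumption that cells run their
   pathways at an efficient minimum, and drains stoichiometrically
   balanced loop fluxes (which carry no physiological information) to
   zero. The result, $v_\mathrm{ref}$, satisfies $S v_\mathrm{ref} = 0$
   to $10^{-8}$, all bounds, and biomass $\ge 10^{-4}$.

## The pharmacokinetic driver

The built-in simulator is deliberately a **four-compartment minimal
model** — gut lumen, central/plasma, liver intracellular, urine sink —
not a whole-body re-implementation: the coupling needs only the
intracellular liver rate vector and a closed mass balance. Seven species
track the isoniazid cascade (isoniazid, acetylisoniazid, isonicotinic
acid, isonicotinoyl glycine, hydrazine, acetylhydrazine,
diacetylhydrazine); eight hepatic Michaelis–Menten reactions connect them
(three NAT2 acetylations, two amidase hydrolyses, glycine conjugation,
CYP2E1 oxidation, NOS2-mediated hydrazine clearance); absorption and
renal elimination are first order; hepatic distribution is flow-limited.
A small first-order extrahepatic hydrolysis of circulating isoniazid
(liberating isonicotinic acid *and* the hydrazine moiety) represents
non-NAT2 elimination outside the liver; without it, no parameter choice
can simultaneously give a slow acetylator a small hepatic-metabolized
fraction *and* only ~half the dose excreted unchanged.

Every species carries one isonicotinyl and/or one hydrazine moiety, so
moiety-wise mass balance is closed *by construction*: compartment amounts
plus cumulative urinary excretion plus the oxidative sinks always sum to
the administered dose (verified to 0.5%, the ODE tolerance bound, in the
test suite). Integration uses `deSolve::lsoda` with absolute tolerance
1e-10 µmol; cumulative reaction and transfer integrals are carried as
extra states so ledgers are exact, not post-hoc quadratures.

**Acetylator phenotypes.** The fast and slow presets are identical except
for the NAT2 Vmax scale (1 vs 0.07), mirroring the polymorphism. The
kinetic constants are fixture constants — *not* literature parameters —
chosen once so that a single 300 mg oral dose (2187.5 µmol) reproduces
the qualitative phenotype pattern: fast acetylators metabolize roughly
two-thirds of the dose hepatically, slow acetylators under a quarter, and
slow acetylators excrete about half the dose unchanged in urine. The
analytic skeleton behind the choice: with hepatic intrinsic clearance
$a k + b$ (k = NAT2 scale, b = amidase), renal clearance $r$ and
NAT2-independent extrahepatic clearance $c$, the three dose-fraction
windows fix $a$, $b/r$, $c/r$ and $k_\mathrm{slow}$ up to scale; Km
values (100–200 µM) keep saturation moderate at the ~55 µM peak plasma
concentration.

**Step size.** The canonical grid is 72 h at 1 min (4321 points), matching
a complete washout. Mean-over-interval resampling preserves the
left-rectangle integral of every rate column exactly, and the coupling is
step-size robust: 1-min and 10-min runs agree within 2% on every reaction
trajectory integral (tested).

## The synthetic fixture

`generate_toy_fixture()` emulates all four input kinds at desk scale: a
24-metabolite / 28-reaction hepatocyte caricature (fasted state: lactate
in, glucose out, lumped oxidation, NADPH shunt, glutathione synthesis,
mitochondrial glycine import, biomass), a matching expression profile
(fixed base intensities with a seed-controlled ±5% jitter), a utilization
table, and a pathway clustering. Two design features serve validation:

* a two-reaction **futile cycle** (cytosol/mitochondria pyruvate
  shuttle) that iMAT may activate but flux minimization must drain;
* a **stoichiometrically disconnected side pathway** (`pathway_b`)
  sharing no metabolite with the core — its reactions provably cannot
  move under any xenobiotic pin, giving an exact-zero pathway score and a
  locality control for the QP.

Uptake bounds are sized so the toy liver can process a full clinical
dose's cofactor demand (peak total xenobiotic rate ~11 µmol·min⁻¹ against
uptake capacities of 100–400 µmol·min⁻¹); the reference state itself uses
only a vanishing fraction of that capacity, as a biomass-minimal fasted
state should. What the fixture does *not* emulate: genome-scale
redundancy (thousands of alternative routes), realistic pathway
granularity, growth-medium complexity, or expression noise structure.
Passing tests therefore demonstrate correctness of the machinery, not
biological validity on real reconstructions — on a genome-scale model the
same code paths apply but solver cost and degeneracy grow.

## Numerical choices

* **QP**: Goldfarb–Idnani dual active set (`quadprog`), with the
  equality system (stoichiometry + pinned rates + zero-width bounds)
  rank-reduced by QR first — stoichiometric matrices routinely carry
  dependent conservation rows, which the solver does not tolerate — and a
  post-hoc residual check over the *full* system so that a dropped
  inconsistent row is reported as infeasibility, never silently ignored.
  KKT residuals are at machine precision for these problem sizes; the
  test suite pins the solution against the analytic pseudoinverse
  projection to 1e-8.
* **LP**: an own dense bounded-variable revised simplex (phase 1 with
  artificials, Dantzig pricing with a Bland fallback after stalls,
  explicit basis inverse with rank-1 updates and periodic
  refactorization). Problem sizes here are tens of variables, so
  robustness was weighted over speed.
* **MILP**: depth-first branch-and-bound over the LP relaxation;
  deterministic by construction (fixed branching order, strict
  incumbent improvement, index-weighted objective).
* **Infeasibility diagnostics**: a phase-1-style slack LP localizes which
  metabolite balances conflict with a pinned rate vector; the error
  object carries the offending metabolites, the timepoint, and the
  partial flux matrix. An opt-in `relax` mode instead scales the pinned
  vector by the largest feasible factor α ∈ [0, 1] (40-step bisection)
  and records α per timepoint — silent constraint dropping would corrupt
  every downstream metric, so relaxation is explicit and logged.
* **Unpinned xenobiotic reactions** at timepoints where the driver
  reports no rate are held at 0 (closed), the conservative reading of
  "no reported flux".
* **Oxidation cofactors**: the oxidation template consumes O₂ only by
  default, with NADPH consumption opt-in; the isoniazid preset enables
  the NADPH variant for CYP2E1 (CYP catalysis is NADPH-dependent) and
  leaves NOS2 at O₂-only. Both are per-spec configurable, since curated
  per-reaction stoichiometries may differ.
* **Transporter templates** (phase III, ATP-driven and sym-/antiport)
  are implemented but not part of the isoniazid preset — no transporter
  energetics belong to this cascade.

## Problem sizes and runtime

All shipped checks run on the toy fixture: reference construction
(~0.2 s), full 72 h coupling at 1 min (4321 QPs, ~3 s), brute-force iMAT
enumeration (2^10 activity patterns, ~10 s). The complete test suite runs
in well under a minute on one CPU.

## Known limitations

* The PK driver is a calibrated toy: its dose-fraction *pattern* is
  phenotype-faithful, but its parameters are not literature values and
  its ledgers are preset-dependent.
* The isoniazid xenobiotic preset reconstructs per-reaction cofactor
  stoichiometry from the generic templates; it is data-driven (JSON) so a
  curated table can replace it verbatim.
* No thermodynamic or enzyme-capacity constraints; no regulatory logic;
  no dynamic metabolite pools inside the network (the PK side owns all
  dynamics).
* SBML support is read-only (Level 3 core + fbc bounds/GPRs); the JSON
  dialect is the canonical round-trip format.
* iMAT is the only context-extraction algorithm offered; expression
  preprocessing is a plain mean across samples.
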
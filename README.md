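# dmoma — drug-induced metabolic perturbation by PK-coupled MOMA

`dmoma` quantifies how the metabolism of a drug perturbs an organ's
endogenous biochemical network. It couples a compartmental
pharmacokinetic (PK) model to an organ-specific constraint-based
metabolic network through their only shared reactions — the xenobiotic
metabolism — and asks, at every minute of a dosing simulation: *what is
the smallest rearrangement of the cell's flux state that can pay the
drug's cofactor bill?*

It is written for systems pharmacologists and constraint-based modelers
who want mechanistic, time-resolved predictions of drug-induced metabolic
burden (e.g. for drug-induced liver injury) rather than static
single-timepoint flux analyses.

## The method

At each timepoint *i* of the PK grid, the engine solves the dynamic
minimization-of-metabolic-adjustment (dMOMA) quadratic program

```
min  (v_i − v_ref)ᵀ (v_i − v_ref)
s.t. S v_i = 0
     lb ≤ v_i ≤ ub
     v_xeno = v_PK(t_i)          (pinned xenobiotic rates)
```

where `S` is the m × r stoichiometric matrix, `v_ref` the unperturbed
reference flux distribution, and `v_PK(t_i)` the intracellular xenobiotic
reaction rates delivered by the PK driver. The xenobiotic reactions carry
only their endogenous cofactor demand (acetylation: acetyl-CoA → CoA;
hydrolysis: H₂O; CYP oxidation: O₂ + NADPH → NADP⁺; glycine conjugation:
glycine; …) — the drug species themselves are balanced on the PK side.

From the resulting flux matrix `v_it` the analytics layer computes
differential fluxes `Δv_it = v_it − v_ref`, integrated perturbations
`P_rxn = ∫|Δv| dt` (and `P_ex`, `P_PBPK`), the significance rule
`P_rxn > ε·t` (ε = 10⁻⁵ µmol·liver⁻¹·min⁻¹), pathway perturbations
`P_MP`, attenuation curves `AT_MP`, pathway scores `PS = P_MP / P_PBPK`
(0 = independence, 0–1 = partial, >1 = aggravation), and signed
exometabolome pool changes.

The reference state comes from expression data: GPR-propagated reaction
scores (AND → min, OR → max), 75th/25th-percentile active/inactive sets,
iMAT context extraction under fasted-state exchange bounds with a minimal
biomass flux of 10⁻⁴, then intracellular flux-sum minimization. A
built-in four-compartment PK simulator of the isoniazid cascade (NAT2
acetylations, amidase hydrolyses, CYP2E1/NOS2 oxidations, glycine
conjugation; Michaelis–Menten kinetics, closed moiety mass balance)
provides fast/slow acetylator presets; externally simulated rate tables
can be supplied as CSV instead.

## Worked example

```r
library(dmoma)

fx  <- generate_toy_fixture(seed = 42, size = "small", dir = "fixture")
net <- load_network(fx$network)
net <- extend_network(net, isoniazid_preset(net))      # splice 8 xenobiotic reactions
ref <- build_reference_state(net, fx$expr, fx$util)
ref
#> reference_state over 36 reactions (epsilon = 1e-05, 12 locked directions)

sim <- simulate_pbpk(acetylator_preset("fast"), duration = 4320, dt = 10)
round(sim$ledger$hepatic_metabolized_fraction, 3)
#> [1] 0.639

fm     <- run_dmoma(ref, sim$rates)
report <- perturbation_report(fm, clusters = fx$cluster_map)
report
#> perturbation_report: 36 reactions, 24 significant (P_rxn > 0.0432); P_PBPK = 2845.844 umol/liver
#> pathway scores:
#>             transport              exchange        central_carbon
#>                1.8210                1.7852                1.5110
#> xenobiotic_metabolism   cofactor_metabolism           unclustered
#>                1.0000                0.0085                0.0001
#>             pathway_b
#>                0.0000
```

Reading the numbers: the fast-acetylator liver metabolizes 63.9% of a
300 mg oral dose. Over 72 h, 24 of the 36 context-network reactions are
significantly altered (their accumulated perturbation exceeds
ε·t = 0.0432 µmol·liver⁻¹). Transport, exchange and central carbon
pathways score above 1 — the drug's cofactor demand is *aggravated*
through them (compensatory rerouting exceeds the inducing xenobiotic
flux) — while cofactor metabolism is only partially perturbed. The
`xenobiotic_metabolism` cluster scores exactly 1 (it *is* the driver),
and the stoichiometrically disconnected control pathway `pathway_b`
scores exactly 0: perturbations do not propagate across a
stoichiometric gap.

Comparing phenotypes (`acetylator_preset("slow")`, then
`compare_runs(report_fast, report_slow)`) shows the slow acetylator's
perturbation is smaller at peak but attenuates much later — the sustained
burden that distinguishes the phenotypes.

A thin CLI covers the same stages
(`Rscript scripts/dmoma.R fixture|run|compare …`), with `run` driven by a
YAML config mirroring `run_config()`.

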
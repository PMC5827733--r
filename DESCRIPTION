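Package: dmoma
Title: Coupling Whole-Body Pharmacokinetics to Genome-Scale Metabolic
    Networks by Dynamic Minimization of Metabolic Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies drug-induced metabolic perturbations in an organ by
    coupling a compartmental pharmacokinetic driver to an organ-specific
    constraint-based metabolic network. Time-resolved xenobiotic reaction
    rates are pinned into the network and a minimization-of-metabolic-
    adjustment quadratic program is solved at every time step against an
    unperturbed reference flux distribution. Includes cofactor-only
    xenobiotic reaction templates for phase I-III drug metabolism, a
    reference-state builder (expression-driven iMAT context extraction and
    intracellular flux minimization), a minimal mass-balanced pharmacokinetic
    simulator of the isoniazid cascade with fast/slow acetylator presets,
    and a perturbation-analytics layer (differential fluxes, integrated
    perturbations, pathway scores, attenuation curves, exometabolome pool
    changes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    quadprog,
    stats,
    tools,
    utils,
    xml2
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
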
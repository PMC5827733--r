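# Small hand-built networks and lazily cached expensive fixtures shared
# across test files.

# A -> B -> C linear chain with an uptake and a secretion exchange.
chain_net <- function(lb_mid = -1000, ub_mid = 1000) {
  metabolic_network(
    metabolites = data.frame(
      id = c("a_e", "a_c", "b_c", "b_e"),
      compartment = c("e", "c", "c", "e")),
    reactions = list(
      list(id = "EX_a", stoichiometry = c(a_e = -1),
           lower_bound = -10, upper_bound = 10),
      list(id = "T_a", stoichiometry = c(a_e = -1, a_c = 1),
           lower_bound = lb_mid, upper_bound = ub_mid),
      list(id = "R_ab", stoichiometry = c(a_c = -1, b_c = 1),
           lower_bound = lb_mid, upper_bound = ub_mid),
      list(id = "T_b", stoichiometry = c(b_c = -1, b_e = 1),
           lower_bound = lb_mid, upper_bound = ub_mid),
      list(id = "EX_b", stoichiometry = c(b_e = -1),
           lower_bound = -10, upper_bound = 10)),
    compartments = c(c = "cytosol", e = "extracellular"),
    id = "chain")
}

# Two isozyme branches from substrate to product, one well-expressed and
# one barely expressed, feeding a biomass sink.
branch_net <- function() {
  metabolic_network(
    metabolites = data.frame(
      id = c("s_e", "s_c", "p_c"),
      compartment = c("e", "c", "c")),
    reactions = list(
      list(id = "EX_s", stoichiometry = c(s_e = -1),
           lower_bound = -10, upper_bound = 0),
      list(id = "T_s", stoichiometry = c(s_e = -1, s_c = 1),
           lower_bound = 0, upper_bound = 10),
      list(id = "R_hi", stoichiometry = c(s_c = -1, p_c = 1),
           lower_bound = 0, upper_bound = 10, gpr = "g_hi"),
      list(id = "R_lo", stoichiometry = c(s_c = -1, p_c = 1),
           lower_bound = 0, upper_bound = 10, gpr = "g_lo"),
      list(id = "BIOMASS", stoichiometry = c(p_c = -1),
           lower_bound = 0, upper_bound = 10, role = "biomass")),
    compartments = c(c = "cytosol", e = "extracellular"),
    id = "branch")
}

# Through-path plus a two-reaction futile cycle.
loop_net <- function() {
  metabolic_network(
    metabolites = data.frame(
      id = c("a_e", "a_c", "b_c"),
      compartment = c("e", "c", "c")),
    reactions = list(
      list(id = "EX_a", stoichiometry = c(a_e = -1),
           lower_bound = -10, upper_bound = 0),
      list(id = "T_a", stoichiometry = c(a_e = -1, a_c = 1),
           lower_bound = 0, upper_bound = 10),
      list(id = "BIOMASS", stoichiometry = c(a_c = -1),
           lower_bound = 0, upper_bound = 10, role = "biomass"),
      list(id = "LOOP_f", stoichiometry = c(a_c = -1, b_c = 1),
           lower_bound = 0, upper_bound = 10),
      list(id = "LOOP_r", stoichiometry = c(b_c = -1, a_c = 1),
           lower_bound = 0, upper_bound = 10)),
    compartments = c(c = "cytosol", e = "extracellular"),
    id = "loop")
}

write_mini_sbml <- function(path = tempfile(fileext = ".xml")) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="mini" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" name="cytosol" constant="true"/>',
    '      <compartment id="e" name="extracellular" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="a_e" compartment="e" constant="false" boundaryCondition="false"/>',
    '      <species id="b_c" compartment="c" constant="false" boundaryCondition="false"/>',
    '    </listOfSpecies>',
    '    <listOfParameters>',
    '      <parameter id="lb0" value="0" constant="true"/>',
    '      <parameter id="lbneg" value="-1000" constant="true"/>',
    '      <parameter id="ub1000" value="1000" constant="true"/>',
    '    </listOfParameters>',
    '    <listOfReactions>',
    '      <reaction id="EX_a" reversible="true" fbc:lowerFluxBound="lbneg" fbc:upperFluxBound="ub1000">',
    '        <listOfReactants>',
    '          <speciesReference species="a_e" stoichiometry="1" constant="true"/>',
    '        </listOfReactants>',
    '      </reaction>',
    '      <reaction id="AB" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">',
    '        <listOfReactants>',
    '          <speciesReference species="a_e" stoichiometry="1" constant="true"/>',
    '        </listOfReactants>',
    '        <listOfProducts>',
    '          <speciesReference species="b_c" stoichiometry="2" constant="true"/>',
    '        </listOfProducts>',
    '        <fbc:geneProductAssociation>',
    '          <fbc:and>',
    '            <fbc:geneProductRef fbc:geneProduct="g1"/>',
    '            <fbc:or>',
    '              <fbc:geneProductRef fbc:geneProduct="g2"/>',
    '              <fbc:geneProductRef fbc:geneProduct="g3"/>',
    '            </fbc:or>',
    '          </fbc:and>',
    '        </fbc:geneProductAssociation>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  path
}

# ---- lazily cached shared objects ------------------------------------

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

fixture_small <- function() cached("fixture_small", {
  generate_toy_fixture(seed = 42, size = "small",
                       dir = file.path(tempdir(), "fx_small"))
})

extended_small <- function() cached("extended_small", {
  fx <- fixture_small()
  net <- load_network(fx$network)
  extend_network(net, isoniazid_preset(net))
})

reference_small <- function() cached("reference_small", {
  fx <- fixture_small()
  build_reference_state(extended_small(), fx$expr, fx$util)
})

pk_sim <- function(phenotype = "fast", dt = 10) {
  cached(paste0("pk_", phenotype, "_", dt),
         simulate_pbpk(acetylator_preset(phenotype),
                       duration = 4320, dt = dt))
}

dmoma_run <- function(phenotype = "fast", dt = 10) {
  cached(paste0("run_", phenotype, "_", dt), {
    series <- pk_sim(phenotype, 1)$rates
    if (dt > 1) series <- resample_rates(series, dt)
    run_dmoma(reference_small(), series)
  })
}

report_small <- function(phenotype = "fast", dt = 10) {
  cached(paste0("report_", phenotype, "_", dt),
         perturbation_report(dmoma_run(phenotype, dt),
                             clusters = fixture_small()$cluster_map))
}
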
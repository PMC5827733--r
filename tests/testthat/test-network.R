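test_that("JSON round-trip preserves structure bit-exactly", {
  fx <- fixture_small()
  net <- load_network(fx$network)
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  net2 <- load_network(path)
  expect_identical(stoichiometric_matrix(net), stoichiometric_matrix(net2))
  expect_identical(lower_bounds(net), lower_bounds(net2))
  expect_identical(upper_bounds(net), upper_bounds(net2))
  expect_identical(reaction_roles(net), reaction_roles(net2))
  expect_identical(vapply(net$reactions, `[[`, "", "gpr"),
                   vapply(net2$reactions, `[[`, "", "gpr"))
  expect_identical(pathway_clusters(net), pathway_clusters(net2))
})

test_that("validation rejects structural defects", {
  mets <- data.frame(id = c("a_c", "b_c"), compartment = "c")
  comp <- c(c = "cytosol")
  ok <- list(list(id = "R1", stoichiometry = c(a_c = -1, b_c = 1),
                  lower_bound = 0, upper_bound = 1))
  expect_s3_class(suppressWarnings(metabolic_network(mets, ok, comp)),
                  "metabolic_network")
  # empty reaction list
  expect_error(metabolic_network(mets, list(), comp),
               class = "dmoma_validation_error")
  # lower bound above upper bound
  bad_lb <- list(list(id = "R1", stoichiometry = c(a_c = -1),
                      lower_bound = 1, upper_bound = 0))
  expect_error(metabolic_network(mets, bad_lb, comp),
               class = "dmoma_validation_error")
  # duplicate reaction ids
  expect_error(metabolic_network(mets, c(ok, ok), comp),
               class = "dmoma_validation_error")
  # reference to an unknown metabolite
  ghost <- list(list(id = "R1", stoichiometry = c(zz_c = -1),
                     lower_bound = 0, upper_bound = 1))
  expect_error(metabolic_network(mets, ghost, comp),
               class = "dmoma_validation_error")
  # exchange reaction touching a cytosolic metabolite
  fake_ex <- list(list(id = "EX", stoichiometry = c(a_c = -1),
                       lower_bound = 0, upper_bound = 1, role = "exchange"))
  expect_error(metabolic_network(mets, fake_ex, comp),
               class = "dmoma_validation_error")
  # isolated metabolite warns but passes
  mets3 <- rbind(mets, data.frame(id = "orphan_c", compartment = "c"))
  expect_warning(expect_warning(metabolic_network(mets3, ok, comp),
                                "orphan_c"),
                 "extracellular")

})

test_that("stoichiometric matrix layout follows the declared orders", {
  net <- chain_net()
  S <- stoichiometric_matrix(net)
  expect_identical(dim(S), c(4L, 5L))
  expect_identical(rownames(S), net$metabolites$id)
  expect_identical(colnames(S), reaction_ids(net))
  # single A -> B conversion column is (-1, +1)
  expect_identical(unname(S[c("a_c", "b_c"), "R_ab"]), c(-1, 1))
  # exchange columns carry exactly one nonzero entry of magnitude 1
  ex <- classify_exchanges(net)$exchange
  for (e in ex) expect_identical(sum(S[, e] != 0), 1L)
  expect_true(all(abs(colSums(S[, ex])) == 1))
})

test_that("exchange classification counts biomass and xenobiotic as intracellular", {
  net <- extended_small()
  cls <- classify_exchanges(net)
  expect_length(cls$exchange, 8L)
  expect_setequal(union(cls$exchange, cls$intracellular), reaction_ids(net))
  expect_length(intersect(cls$exchange, cls$intracellular), 0L)
  roles <- reaction_roles(net)
  expect_true(all(names(roles)[roles %in% c("biomass", "xenobiotic")] %in%
                    cls$intracellular))
})

test_that("a network without extracellular compartment has no exchanges and warns", {
  mets <- data.frame(id = c("a_c", "b_c"), compartment = "c")
  net <- metabolic_network(
    mets, list(list(id = "R1", stoichiometry = c(a_c = -1, b_c = 1),
                    lower_bound = 0, upper_bound = 1)),
    c(c = "cytosol"), validate = FALSE)
  expect_warning(cls <- classify_exchanges(net), "extracellular")
  expect_length(cls$exchange, 0L)
})

test_that("missing bounds default to +-1000 and roles are inferred", {
  net <- metabolic_network(
    data.frame(id = c("a_e", "a_c"), compartment = c("e", "c")),
    list(list(id = "EX_a", stoichiometry = c(a_e = -1)),
         list(id = "T_a", stoichiometry = c(a_e = -1, a_c = 1)),
         list(id = "biomass_rxn", stoichiometry = c(a_c = -1))),
    c(c = "cytosol", e = "extracellular"))
  expect_identical(unname(lower_bounds(net)), rep(-1000, 3))
  expect_identical(unname(upper_bounds(net)), rep(1000, 3))
  expect_identical(unname(reaction_roles(net)),
                   c("exchange", "intracellular", "biomass"))
})

test_that("the SBML reader recovers compartments, stoichiometry, fbc bounds and GPRs", {
  net <- load_network(write_mini_sbml())
  expect_identical(sort(names(net$compartments)), c("c", "e"))
  expect_identical(net$extracellular, "e")
  S <- stoichiometric_matrix(net)
  expect_identical(unname(S[c("a_e", "b_c"), "AB"]), c(-1, 2))
  expect_identical(unname(lower_bounds(net)[c("EX_a", "AB")]), c(-1000, 0))
  expect_identical(net$reactions[["AB"]]$gpr, "(g1 and (g2 or g3))")
  expect_identical(unname(reaction_roles(net)["EX_a"]), "exchange")
})

test_that("flux distributions must cover the reaction set exactly", {
  net <- chain_net()
  v <- setNames(rep(0, 5), reaction_ids(net))
  expect_s3_class(flux_distribution(v, net), "flux_distribution")
  expect_error(flux_distribution(v[-1], net),
               class = "dmoma_validation_error")
})
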
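test_that("GPR evaluation follows complex/isozyme semantics", {
  net <- suppressWarnings(metabolic_network(
    data.frame(id = c("a_c", "b_c"), compartment = "c"),
    list(list(id = "R_and", stoichiometry = c(a_c = -1, b_c = 1),
              lower_bound = 0, upper_bound = 1, gpr = "g1 and g2"),
         list(id = "R_or", stoichiometry = c(a_c = -1, b_c = 1),
              lower_bound = 0, upper_bound = 1, gpr = "g1 or g2"),
         list(id = "R_nested", stoichiometry = c(a_c = -1, b_c = 1),
              lower_bound = 0, upper_bound = 1,
              gpr = "(g1 and g2) or g3"),
         list(id = "R_none", stoichiometry = c(a_c = -1, b_c = 1),
              lower_bound = 0, upper_bound = 1)),
    c(c = "cytosol")))
  expr <- c(g1 = 0.8, g2 = 0.2, g3 = 0.5)
  sc <- reaction_scores(net, expr)
  # normalized to max -> g1 = 1, g2 = 0.25, g3 = 0.625
  expect_equal(sc$scores[["R_and"]], 0.25)
  expect_equal(sc$scores[["R_or"]], 1)
  expect_equal(sc$scores[["R_nested"]], 0.625)
  expect_false("R_none" %in% names(sc$scores))

  # unknown genes drop out of min/max with a warning
  expect_warning(sc2 <- reaction_scores(net, c(g1 = 0.8, g3 = 0.5)),
                 "g2")
  expect_equal(sc2$scores[["R_and"]], 1)  # min over known genes only
})

test_that("threshold sets split at the 75th/25th percentile of nonzero scores", {
  sc <- structure(list(
    scores = setNames(seq(0.1, 1, by = 0.1), paste0("R", 1:10)),
    active = character(0), inactive = character(0)),
    class = "reaction_score_set")
  out <- threshold_sets(sc)
  # type-7 quantiles of 0.1..1.0: q75 = 0.775, q25 = 0.325
  expect_setequal(out$active, c("R8", "R9", "R10"))
  expect_setequal(out$inactive, c("R1", "R2", "R3"))

  # zero-scored reactions land in the inactive set
  sc$scores[["R0"]] <- 0
  out2 <- threshold_sets(sc)
  expect_true("R0" %in% out2$inactive)

  # degenerate uniform scores: ties break toward active with a warning
  scu <- sc; scu$scores <- setNames(rep(0.5, 5), paste0("U", 1:5))
  expect_warning(outu <- threshold_sets(scu), "degenerate")
  expect_setequal(outu$active, paste0("U", 1:5))
  expect_length(intersect(outu$active, outu$inactive), 0L)

  # all-zero scores carry no signal
  scz <- sc; scz$scores <- setNames(rep(0, 4), paste0("Z", 1:4))
  expect_error(threshold_sets(scz), class = "dmoma_validation_error")

  # a single nonzero score becomes the active set (degenerate quantiles
  # coincide, hence the tie-break warning)
  sc1 <- sc; sc1$scores <- c(only = 0.4)
  expect_warning(out1 <- threshold_sets(sc1), "degenerate")
  expect_identical(out1$active, "only")
})

test_that("fasted-state constraints close unlisted exchanges and keep signs", {
  fx <- fixture_small()
  net <- load_network(fx$network)
  con <- apply_fasted_state(net, fx$util)
  # glucose is secretion-only, oxygen uptake-only
  expect_identical(unname(lower_bounds(con)["EX_glc"]), 0)
  expect_true(upper_bounds(con)[["EX_glc"]] > 0)
  expect_identical(unname(upper_bounds(con)["EX_o2"]), 0)
  expect_true(lower_bounds(con)[["EX_o2"]] < 0)
  # an exchange missing from the table is closed
  util2 <- fx$util[fx$util$exchange_id != "EX_b1", ]
  con2 <- apply_fasted_state(net, util2)
  expect_identical(unname(lower_bounds(con2)["EX_b1"]), 0)
  expect_identical(unname(upper_bounds(con2)["EX_b1"]), 0)
  # intracellular ids are rejected; an empty table warns
  bad <- data.frame(exchange_id = "LDH", lb = 0, ub = 1)
  expect_error(apply_fasted_state(net, bad),
               class = "dmoma_validation_error")
  expect_warning(apply_fasted_state(net, fx$util[0, ]), "empty")
})

test_that("iMAT picks the well-expressed branch and matches brute force", {
  net <- branch_net()
  sets <- threshold_sets(reaction_scores(net, c(g_hi = 1000, g_lo = 10)))
  expect_identical(sets$active, "R_hi")
  expect_identical(sets$inactive, "R_lo")
  fit <- imat_fit(net, sets, eps = 1e-5, biomass_min = 1e-4)
  expect_identical(fit$objective, 2L)
  expect_true(fit$flux[["R_hi"]] >= 1e-5)
  expect_true(abs(fit$flux[["R_lo"]]) <= 1e-5)
  expect_identical(fit$objective,
                   imat_brute_force(net, sets, 1e-5, 1e-4))
})

test_that("iMAT handles degenerate set inputs", {
  net <- branch_net()
  empty <- structure(list(scores = numeric(0), active = character(0),
                          inactive = character(0)),
                     class = "reaction_score_set")
  fit <- imat_fit(net, empty)
  expect_identical(fit$objective, 0)
  expect_true(fit$flux[["BIOMASS"]] >= 1e-4)
  # eps beyond every feasible flux: no active reaction satisfiable
  sets <- threshold_sets(reaction_scores(net, c(g_hi = 1000, g_lo = 10)))
  expect_warning(fit2 <- imat_fit(net, sets, eps = 100), "threshold too large")
  expect_length(fit2$active_satisfied, 0L)
})

test_that("iMAT respects the biomass minimum or reports infeasibility", {
  net <- branch_net()
  sets <- threshold_sets(reaction_scores(net, c(g_hi = 1000, g_lo = 10)))
  fit <- imat_fit(net, sets, biomass_min = 1e-4)
  expect_true(fit$flux[["BIOMASS"]] >= 1e-4 - 1e-12)
  expect_error(imat_fit(net, sets, biomass_min = 50),
               class = "dmoma_infeasible_error")
})

test_that("flux minimization drains futile cycles and preserves exchanges", {
  net <- loop_net()
  v_imat <- setNames(c(-1, 1, 1, 3, 3), reaction_ids(net))
  ref <- minimize_intracellular_flux(net, v_imat, eps = 1e-5)
  expect_equal(ref$v_ref[["LOOP_f"]], 0, tolerance = 1e-10)
  expect_equal(ref$v_ref[["LOOP_r"]], 0, tolerance = 1e-10)
  expect_identical(ref$v_ref[["EX_a"]], -1)      # exchange fixed exactly
  expect_equal(ref$v_ref[["BIOMASS"]], 1, tolerance = 1e-10)
  # objective never increases; already-minimal input is a fixed point
  cls <- classify_exchanges(net)
  sum_int <- function(v) sum(abs(v[cls$intracellular]))
  expect_lte(sum_int(ref$v_ref), sum_int(v_imat))
  ref2 <- minimize_intracellular_flux(net, as.numeric(ref$v_ref) |>
                                        setNames(names(ref$v_ref)))
  expect_equal(as.numeric(ref2$v_ref), as.numeric(ref$v_ref),
               tolerance = 1e-9)
})

test_that("the reference state satisfies its defining invariants", {
  ref <- reference_small()
  S <- stoichiometric_matrix(ref$network)
  v <- as.numeric(ref$v_ref)
  expect_lt(max(abs(S %*% v)), 1e-8)
  expect_true(all(v >= lower_bounds(ref$network) - 1e-9))
  expect_true(all(v <= upper_bounds(ref$network) + 1e-9))
  expect_gte(ref$v_ref[["BIOMASS"]], 1e-4 - 1e-12)
  # locked directions honored
  for (rid in names(ref$fixed_directions))
    expect_gte(ref$v_ref[[rid]] * ref$fixed_directions[[rid]], -1e-12)
  # xenobiotic reactions are present, closed, and at zero
  roles <- reaction_roles(ref$network)
  xeno <- names(roles)[roles == "xenobiotic"]
  expect_length(xeno, 8L)
  expect_true(all(ref$v_ref[xeno] == 0))
})
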
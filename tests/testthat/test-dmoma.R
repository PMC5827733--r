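test_that("pinning sets both bounds and rejects non-xenobiotic targets", {
  net <- extended_small()
  pinned <- pin_xenobiotic(net, c(NAT2_INH = 0.3))
  expect_identical(unname(lower_bounds(pinned)["NAT2_INH"]), 0.3)
  expect_identical(unname(upper_bounds(pinned)["NAT2_INH"]), 0.3)
  # all other bounds untouched
  others <- setdiff(reaction_ids(net), "NAT2_INH")
  expect_identical(lower_bounds(pinned)[others], lower_bounds(net)[others])
  expect_error(pin_xenobiotic(net, c(LDH = 0.1)),
               class = "dmoma_validation_error")
  expect_error(pin_xenobiotic(net, c(nope = 0.1)),
               class = "dmoma_validation_error")
})

test_that("zero pinned rates reproduce the reference exactly", {
  ref <- reference_small()
  roles <- reaction_roles(ref$network)
  xeno <- names(roles)[roles == "xenobiotic"]
  v <- solve_moma_step(pin_xenobiotic(ref$network,
                                      setNames(rep(0, 8), xeno)), ref)
  expect_lt(max(abs(as.numeric(v) - as.numeric(ref$v_ref))), 1e-9)
})

test_that("the QP solution matches the analytic KKT projection", {
  # unconstrained-interior cases on small nets: wide bounds, a pinned
  # drain, compare against the pseudoinverse least-squares solution
  net <- chain_net()
  S <- stoichiometric_matrix(net)
  vref <- c(EX_a = -2, T_a = 2, R_ab = 2, T_b = 2, EX_b = 2)
  ref <- structure(list(network = net,
                        v_ref = flux_distribution(vref, net),
                        epsilon = 1e-5, fixed_directions = numeric(0),
                        biomass_id = NULL),
                   class = "reference_state")
  for (rate in c(0.5, 1.5, 3)) {
    pin <- net
    pin$reactions[["R_ab"]]$lower_bound <- rate
    pin$reactions[["R_ab"]]$upper_bound <- rate
    got <- as.numeric(solve_moma_step(pin, ref))
    want <- kkt_project(S, vref, pin_idx = 3, rates = rate)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("infeasible pins report the conflicting metabolite balances", {
  ref <- reference_small()
  # glycine conjugation beyond the glycine uptake bound (100)
  err <- tryCatch(
    solve_moma_step(pin_xenobiotic(ref$network, c(GLYAT_INA = 500)), ref),
    condition = function(c) c)
  expect_s3_class(err, "dmoma_infeasible_step")
  expect_true(length(err$metabolites) > 0)
  expect_true(any(grepl("gly", err$metabolites)))
})

test_that("run_dmoma propagates infeasibility with timepoint and partial results", {
  ref <- reference_small()
  series <- rate_time_series(
    times = 0:3,
    rates = cbind(GLYAT_INA = c(0, 0, 500, 500)))
  err <- tryCatch(run_dmoma(ref, series), condition = function(c) c)
  expect_s3_class(err, "dmoma_infeasible_step")
  expect_identical(err$timepoint, 3L)
  expect_identical(ncol(err$partial), 2L)
  # relax mode scales the rate down to the feasible boundary instead
  fm <- run_dmoma(ref, series, relax = TRUE)
  expect_equal(fm$alpha[1:2], c(1, 1))
  expect_lt(fm$alpha[3], 1)
  expect_gt(fm$alpha[3], 0)
  S <- stoichiometric_matrix(ref$network)
  expect_lt(max(abs(S %*% fm$fluxes)), 1e-8)
})

test_that("an all-zero series yields columns identical to the reference", {
  ref <- reference_small()
  series <- rate_time_series(times = seq(0, 990, by = 10),
                             rates = matrix(0, 100, 1,
                                            dimnames = list(NULL, "NAT2_INH")))
  fm <- run_dmoma(ref, series)
  expect_identical(ncol(fm$fluxes), 100L)
  expect_true(all(fm$fluxes == as.numeric(ref$v_ref)))
})

test_that("driving non-xenobiotic reactions is rejected", {
  ref <- reference_small()
  series <- rate_time_series(times = 0:2,
                             rates = cbind(LDH = c(0, 1, 0)))
  expect_error(run_dmoma(ref, series), class = "dmoma_validation_error")
})

test_that("perturbations stay local: disconnected reactions never move", {
  # pathway_b shares no metabolite with the perturbed subnetwork
  fm <- dmoma_run("fast", 10)
  ref <- reference_small()
  b_ids <- intersect(c("EX_b1", "B1t", "B12", "B2t", "EX_b2"),
                     rownames(fm$fluxes))
  for (rid in b_ids)
    expect_lt(max(abs(fm$fluxes[rid, ] - ref$v_ref[[rid]])), 1e-9)
})

test_that("pinned trajectories equal the driving rates to machine precision", {
  fm <- dmoma_run("fast", 10)
  series <- resample_rates(pk_sim("fast", 1)$rates, 10)
  for (j in colnames(series$rates))
    expect_identical(unname(fm$fluxes[j, ]), unname(series$rates[, j]))
})

test_that("every dMOMA column is a steady state within bounds", {
  fm <- dmoma_run("fast", 10)
  S <- stoichiometric_matrix(fm$ref$network)
  expect_lt(max(abs(S %*% fm$fluxes)), 1e-8)
  lb <- lower_bounds(fm$ref$network); ub <- upper_bounds(fm$ref$network)
  expect_true(all(fm$fluxes >= lb - 1e-9))
  # pinned xenobiotic columns exceed their closed [0,0] bounds by design;
  # every other reaction respects the network bounds
  roles <- reaction_roles(fm$ref$network)
  endo <- names(roles)[roles != "xenobiotic"]
  expect_true(all(fm$fluxes[endo, ] <= ub[endo] + 1e-9))
})
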
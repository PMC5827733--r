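make_delta <- function(values, rids = paste0("R", seq_len(nrow(values)))) {
  matrix(values, nrow = nrow(values), dimnames = list(rids, NULL))
}

test_that("differential fluxes are exact elementwise differences", {
  fm <- dmoma_run("fast", 10)
  delta <- differential_fluxes(fm)
  # independent recomputation by plain subtraction
  vref <- as.numeric(fm$ref$v_ref[rownames(fm$fluxes)])
  expect_identical(delta, sweep(fm$fluxes, 1, vref))
  expect_true(all(differential_fluxes(
    structure(list(fluxes = matrix(rep(vref, 3), ncol = 3,
                                   dimnames = list(names(fm$ref$v_ref), NULL)),
                   ref = fm$ref), class = "flux_matrix")) == 0))
})

test_that("integrated perturbation is the left-rectangle absolute sum", {
  # constant |delta| = 0.5 over 10 min of 1-min steps -> P = 5
  d <- make_delta(matrix(0.5, 1, 11))
  expect_equal(unname(integrate_perturbation(d, 1, "rxn")), 5)
  # alternating +-1 integrates the magnitude, not the net
  d2 <- make_delta(matrix(c(rep(c(1, -1), 5), 1), 1))
  expect_equal(unname(integrate_perturbation(d2, 1, "rxn")), 10)
  # triangular pulse (base 20 min, height 5): closed-form area 50; the
  # rectangle sum agrees within one step's error bound (here exactly, by
  # symmetry)
  tri <- c(seq(0, 5, by = 0.5), seq(4.5, 0, by = -0.5))
  d3 <- make_delta(matrix(tri, 1))
  p3 <- unname(integrate_perturbation(d3, 1, "rxn"))
  expect_lte(abs(p3 - 50), max(tri) * 1)
  expect_equal(p3, sum(tri[-length(tri)]))
})

test_that("pbpk and exchange variants aggregate over the right roles", {
  roles <- c(R1 = "intracellular", EX1 = "exchange", X1 = "xenobiotic",
             X2 = "xenobiotic")
  d <- make_delta(rbind(c(1, 1, 0), c(0, 2, 0), c(1, 0, 0), c(0, 3, 0)),
                  names(roles))
  expect_equal(integrate_perturbation(d, 2, "pbpk", roles = roles),
               (1 + 3) * 2)
  expect_equal(integrate_perturbation(d, 2, "ex", roles = roles),
               c(EX1 = 4))
  expect_error(integrate_perturbation(d, 2, "ex"),
               class = "dmoma_validation_error")
})

test_that("significance uses a strict threshold at eps * t", {
  p <- c(a = 0.05, b = 0.0432, c = 0, d = 0.04321)
  sig <- significance_mask(p, eps = 1e-5, t_total = 4320)
  expect_setequal(sig, c("a", "d"))      # 0.0432 is NOT significant
  expect_length(significance_mask(c(x = 0, y = 0), 1e-5, 4320), 0L)
})

test_that("pathway perturbation sums only significant members", {
  clusters <- c(r1 = "A", r2 = "A", r3 = "B")
  p <- c(r1 = 0.1, r2 = 0.2, r3 = 0.4)
  pm <- pathway_perturbation(p, sig = c("r1", "r2"), clusters)
  expect_equal(pm, c(A = 0.3, B = 0))
  # brute-force equivalence on a real run
  rep <- report_small("fast", 10)
  for (cl in names(rep$p_mp)) {
    members <- names(rep$clusters)[rep$clusters == cl]
    expect_equal(unname(rep$p_mp[[cl]]),
                 sum(rep$p_rxn[intersect(members, rep$significant)]))
  }
  # never exceeds the unfiltered cluster sum
  for (cl in names(rep$p_mp)) {
    members <- names(rep$clusters)[rep$clusters == cl]
    expect_lte(rep$p_mp[[cl]], sum(rep$p_rxn[members]) + 1e-12)
  }
})

test_that("attenuation curves normalize, ramp and saturate correctly", {
  expect_equal(attenuation_curve(rep(1, 10)), seq(0.1, 1, by = 0.1))
  expect_equal(attenuation_curve(c(5, rep(0, 9))), rep(1, 10))
  expect_warning(empty <- attenuation_curve(rep(0, 5)), "undefined")
  expect_length(empty, 0L)
  # a narrow pulse attenuates earlier than a wide one
  narrow <- attenuation_curve(c(8, 2, 0, 0, 0, 0, 0, 0, 0, 0))
  wide <- attenuation_curve(rep(1, 10))
  expect_lt(min(which(narrow >= 0.9)), min(which(wide >= 0.9)))
})

test_that("pathway scores implement the zero / partial / aggravation semantics", {
  expect_equal(pathway_score(c(A = 0, B = 2, C = 0.5), 1),
               c(A = 0, B = 2, C = 0.5))
  expect_equal(unname(pathway_score(c(A = 3), 3)), 1)
  expect_equal(pathway_score(c(A = 0, B = 0), 0), c(A = 0, B = 0))
  expect_error(pathway_score(c(A = 1), 0),
               class = "dmoma_validation_error")
})

test_that("altered fraction counts strict exceedances per timepoint", {
  d <- make_delta(rbind(c(0, 1, 0), c(0, 2e-5, 0)), c("a", "b"))
  expect_equal(altered_fraction(d, 1e-5), c(0, 1, 0))
  d2 <- make_delta(matrix(0, 100, 3), paste0("r", 1:100))
  d2[1, ] <- 1
  expect_equal(altered_fraction(d2, 1e-5), c(0.01, 0.01, 0.01))
})

test_that("exometabolome pools separate signed and absolute changes", {
  roles <- c(EX1 = "exchange", EX2 = "exchange", R1 = "intracellular")
  # EX1 secretes 0.1 for 600 of 601 one-minute steps -> +60 umol
  d <- make_delta(rbind(rep(0.1, 601),
                        c(rep(1, 300), rep(-1, 300), 0),
                        rep(9, 601)), names(roles))
  pools <- exometabolome_pools(d, 1, roles)
  ex1 <- pools[pools$exchange_id == "EX1", ]
  expect_equal(ex1$pool_change, 60)
  expect_equal(ex1$hepatic_utilization, -60)
  expect_identical(ex1$direction, "increased")
  ex2 <- pools[pools$exchange_id == "EX2", ]
  expect_equal(ex2$pool_change, 0)
  expect_equal(ex2$p_ex_abs, 600)
  expect_identical(ex2$direction, "unchanged")
  expect_false("R1" %in% pools$exchange_id)
  # triangle inequality on a real run
  rep <- report_small("fast", 10)
  expect_true(all(abs(rep$pools$pool_change) <=
                    rep$pools$p_ex_abs + 1e-9))
})

test_that("a full report satisfies its cross-metric invariants", {
  rep <- report_small("fast", 10)
  expect_true(all(rep$altered_fraction >= 0 & rep$altered_fraction <= 1))
  expect_true(all(rep$pathway_scores >= 0))
  # the xenobiotic cluster contains exactly the driver reactions, so its
  # perturbation equals P_PBPK and its score is 1
  expect_equal(unname(rep$pathway_scores[["xenobiotic_metabolism"]]), 1)
  if (nrow(rep$at_mp)) {
    expect_true(all(diff(t(rep$at_mp)) >= -1e-12))
    expect_equal(unname(rep$at_mp[, ncol(rep$at_mp)]),
                 rep(1, nrow(rep$at_mp)), tolerance = 1e-9)
  }
})

test_that("fast runs peak higher and attenuate earlier than slow runs", {
  rep_f <- report_small("fast", 10)
  rep_s <- report_small("slow", 10)
  expect_gt(max(rep_f$altered_fraction), max(rep_s$altered_fraction) - 1e-12)
  # time at which the xenobiotic cluster reaches 90% attenuation
  t90 <- function(rep) {
    at <- rep$at_mp["xenobiotic_metabolism", ]
    rep$at_times[min(which(at >= 0.9))]
  }
  expect_lt(t90(rep_f), t90(rep_s))
})

test_that("comparing runs yields signed differences and a zero self-diff", {
  rep_f <- report_small("fast", 10)
  rep_s <- report_small("slow", 10)
  self <- compare_runs(rep_f, rep_f)
  expect_true(all(self$pathway_scores$diff == 0))
  expect_true(all(self$pools$diff == 0))
  cmp <- compare_runs(rep_f, rep_s)
  expect_true(any(cmp$pathway_scores$diff != 0))
  ps <- cmp$pathway_scores
  expect_equal(ps$diff, ps$ps_b - ps$ps_a)
})
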
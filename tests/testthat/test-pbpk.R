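test_that("moiety mass balance closes at every output time", {
  sim <- pk_sim("fast", 10)
  am <- sim$amounts
  sp_iso <- c("INH", "ACINH", "INA", "INGLY")
  iso <- am$gut
  for (s in sp_iso)
    iso <- iso + am[[paste0("P_", s)]] + am[[paste0("L_", s)]] +
      am[[paste0("U_", s)]]
  dose <- sim$ledger$dose_umol
  expect_lt(max(abs(iso - dose)) / dose, 0.005)
  # hydrazine moiety: every species except INA/INGLY carries one, and the
  # oxidative sinks account for cleared moieties
  hz <- am$gut + am$CUM_CYP2E1_ACHZ + am$CUM_NOS2_HZ
  for (s in c("INH", "ACINH", "HZ", "ACHZ", "DIACHZ"))
    hz <- hz + am[[paste0("P_", s)]] + am[[paste0("L_", s)]] +
      am[[paste0("U_", s)]]
  expect_lt(max(abs(hz - dose)) / dose, 0.005)
})

test_that("a zero dose produces identically zero rates and ledgers", {
  m <- acetylator_preset("fast", dose_umol = 0)
  sim <- simulate_pbpk(m, duration = 120, dt = 10)
  expect_true(all(sim$rates$rates == 0))
  expect_true(all(sim$ledger$urinary_fraction %in% c(0, NaN)) ||
                sim$ledger$dose_umol == 0)
  expect_true(all(sim$amounts[nrow(sim$amounts), -1] == 0))
})

test_that("fast and slow presets differ only in the NAT2 scale", {
  f <- acetylator_preset("fast"); s <- acetylator_preset("slow")
  expect_identical(f[setdiff(names(f), "phenotype")],
                   s[setdiff(names(s), "phenotype")])
  expect_identical(f$phenotype$label, "fast")
  expect_identical(s$phenotype$label, "slow")
  expect_gt(f$phenotype$nat2_vmax_scale, s$phenotype$nat2_vmax_scale)
  expect_gt(s$phenotype$nat2_vmax_scale, 0)
})

test_that("acetylator phenotypes land in their physiological windows", {
  fast <- pk_sim("fast", 10)$ledger
  slow <- pk_sim("slow", 10)$ledger
  expect_gte(fast$hepatic_metabolized_fraction, 0.55)
  expect_lte(fast$hepatic_metabolized_fraction, 0.75)
  expect_gte(slow$hepatic_metabolized_fraction, 0.10)
  expect_lte(slow$hepatic_metabolized_fraction, 0.25)
  expect_gte(slow$urinary_fraction[["INH"]], 0.45)
  expect_lte(slow$urinary_fraction[["INH"]], 0.60)
})

test_that("repeated dosing appends events and conserves the total dose", {
  m <- multi_dose(acetylator_preset("fast"), n_doses = 7, interval = 1440)
  expect_identical(m$doses$time, 1440 * (0:6))
  expect_identical(m$doses$amount, rep(2187.5, 7))
  expect_identical(multi_dose(acetylator_preset("fast"), 1, 1440)$doses,
                   acetylator_preset("fast")$doses)
  expect_error(multi_dose(acetylator_preset("fast"), 2, 0),
               class = "dmoma_validation_error")
  sim <- simulate_pbpk(m, duration = 7 * 1440 + 2880, dt = 10)
  expect_equal(sim$ledger$dose_umol, 7 * 2187.5)
  expect_equal(sim$ledger$isonicotinyl_recovery, 1, tolerance = 0.005)
})

test_that("rate tables round-trip and malformed inputs are rejected", {
  sim <- pk_sim("fast", 10)
  path <- tempfile(fileext = ".csv")
  write_rate_table(sim$rates, path)
  back <- read_rate_table(path)
  expect_equal(back$rates, sim$rates$rates, tolerance = 1e-12)
  expect_identical(back$times, sim$rates$times)

  tab <- utils::read.csv(path, check.names = FALSE)
  # missing time column
  t1 <- tempfile(fileext = ".csv")
  utils::write.csv(tab[-1], t1, row.names = FALSE)
  expect_error(read_rate_table(t1), class = "dmoma_format_error")
  # NaN cell
  t2 <- tempfile(fileext = ".csv"); tab2 <- tab; tab2[3, 2] <- NA
  utils::write.csv(tab2, t2, row.names = FALSE)
  expect_error(read_rate_table(t2), class = "dmoma_format_error")
  # negative rate
  t3 <- tempfile(fileext = ".csv"); tab3 <- tab; tab3[3, 2] <- -1
  utils::write.csv(tab3, t3, row.names = FALSE)
  expect_error(read_rate_table(t3), class = "dmoma_format_error")
  # single row cannot be integrated
  t4 <- tempfile(fileext = ".csv")
  utils::write.csv(tab[1, ], t4, row.names = FALSE)
  expect_error(read_rate_table(t4), class = "dmoma_validation_error")
  # non-uniform grid
  t5 <- tempfile(fileext = ".csv"); tab5 <- tab[-3, ]
  utils::write.csv(tab5, t5, row.names = FALSE)
  expect_error(read_rate_table(t5), class = "dmoma_validation_error")
})

test_that("resampling preserves column integrals and handles the identity", {
  pulse <- rate_time_series(
    times = 0:10,
    rates = cbind(X = c(0, 0, 6, 6, 3, 0, 0, 0, 1, 1, 0)))
  rs <- resample_rates(pulse, 2)
  # hand-computed pair means of the 10 fine intervals
  expect_identical(unname(rs$rates[, "X"]), c(0, 6, 1.5, 0, 1, 0))
  expect_equal(lr_integral(rs$rates[, "X"], 2),
               lr_integral(pulse$rates[, "X"], 1))
  expect_identical(resample_rates(pulse, 1), pulse)
  expect_error(resample_rates(pulse, 3.5),
               class = "dmoma_validation_error")

  sim <- pk_sim("fast", 1)
  rs10 <- resample_rates(sim$rates, 10)
  for (j in colnames(rs10$rates))
    expect_equal(lr_integral(rs10$rates[, j], 10),
                 lr_integral(sim$rates$rates[, j], 1),
                 tolerance = 1e-9)
})

test_that("halving the output step leaves cumulative urinary fractions stable", {
  u2 <- simulate_pbpk(acetylator_preset("fast"), duration = 1440,
                      dt = 2)$ledger$urinary_fraction
  u1 <- simulate_pbpk(acetylator_preset("fast"), duration = 1440,
                      dt = 1)$ledger$urinary_fraction
  expect_lt(max(abs(u1 - u2)), 0.001)
})

test_that("rates stay non-negative everywhere", {
  expect_true(all(pk_sim("fast", 10)$rates$rates >= 0))
  expect_true(all(pk_sim("slow", 10)$rates$rates >= 0))
})
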
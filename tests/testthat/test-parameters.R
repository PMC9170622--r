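test_that("rate-to-probability conversion is exact, bounded and monotone", {
  expect_identical(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.0209, 1), 1 - exp(-0.0209))
  expect_equal(rate_to_probability(0.0209, 1), 0.020683, tolerance = 1e-4)
  expect_equal(rate_to_probability(10, 1), 0.9999546, tolerance = 1e-7)
  r <- seq(0, 5, by = 0.01)
  p <- rate_to_probability(r)
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(diff(p) > 0))
  expect_error(rate_to_probability(-0.1), "non-negative")
})

test_that("age-band lookup returns the printed rates at printed ages", {
  p1 <- brca_parameters("BRCA1")
  p2 <- brca_parameters("BRCA2")
  expect_equal(lookup_rate(p1$rates, "df_bc", 45), 0.0309)
  expect_equal(lookup_rate(p2$rates, "df_oc", 35), 0.0000)
  expect_equal(lookup_rate(p1$rates, "mbc_death", 75), 0.2608)
  expect_equal(lookup_rate(p1$rates, "oc_death", 66), 0.1983)
  expect_equal(lookup_rate(p2$rates, "df_bc", 55), 0.0448)
  expect_equal(lookup_rate(p1$rates, "bc_mbc", 80), 0.0278)
})

test_that("band boundaries are inclusive and resolve to the lower band", {
  p1 <- brca_parameters("BRCA1")
  # age on a printed upper bound belongs to that band
  expect_equal(lookup_rate(p1$rates, "df_bc", 40), 0.0248)  # 31-40
  expect_equal(lookup_rate(p1$rates, "df_bc", 50), 0.0309)  # 41-50
  expect_equal(lookup_rate(p1$rates, "df_bc", 60), 0.0269)  # 51-60
  expect_equal(lookup_rate(p1$rates, "df_bc", 61), 0.0167)  # open-ended band
  expect_equal(lookup_rate(p1$rates, "bc_death", 49), 0.0209)
  expect_equal(lookup_rate(p1$rates, "bc_death", 50), 0.0318)
  expect_equal(lookup_rate(p1$rates, "bc_death", 70), 0.1066)
  expect_error(lookup_rate(p1$rates, "df_oc", 20), "not covered")
  expect_error(lookup_rate(p1$rates, "no_such", 40), "unknown transition")
})

test_that("rates shared between mutations are duplicated in both files", {
  p1 <- brca_parameters("BRCA1")
  p2 <- brca_parameters("BRCA2")
  for (tr in c("bc_death", "mbc_death", "oc_death", "bc_mbc")) {
    t1 <- p1$rates[p1$rates$transition == tr, c("age_lo", "rate")]
    t2 <- p2$rates[p2$rates$transition == tr, c("age_lo", "rate")]
    expect_equal(t1, t2, ignore_attr = TRUE)
  }
})

test_that("hazard-ratio application is multiplicative", {
  expect_equal(apply_hazard_ratio(0.0155, 1.0), 0.0155)
  expect_equal(apply_hazard_ratio(0.0155, 0.28), 0.00434)
  expect_equal(apply_hazard_ratio(0.0309, 0.09), 0.002781)
  expect_error(apply_hazard_ratio(-1, 0.5), "non-negative")
})

test_that("chemoprevention only reduces the HR+ fraction of incidence", {
  mix1 <- subtype_mix("BRCA1")
  mix2 <- subtype_mix("BRCA2")
  expect_equal(sum(mix1), 1)
  expect_equal(mix1[["tnbc"]], 0.70)
  expect_equal(mix2[["hr_pos"]], 0.80)
  r <- 0.0285
  expect_equal(cp_effective_bc_rate(r, mix1, 1.0), r)
  expect_equal(cp_effective_bc_rate(0.0330, mix2, 0.31), 0.0330 * 0.448)
  expect_equal(cp_effective_bc_rate(0.0309, mix1, 0.31), 0.0309 * 0.862)
  # never exceeds the base rate; equality iff no effect or no HR+ fraction
  for (hr in c(0, 0.31, 0.7, 1)) {
    adj <- cp_effective_bc_rate(r, mix1, hr)
    expect_lte(adj, r)
    if (hr < 1) expect_lt(adj, r)
  }
  expect_equal(cp_effective_bc_rate(r, c(hr_pos = 0, tnbc = 0.9, her2 = 0.1), 0.31), r)
})

test_that("malformed parameter files are rejected with located errors", {
  dir <- withr::local_tempdir()
  file.copy(system.file("extdata", "params", c("hazard_ratios.csv", "utilities.csv"),
                        package = "brcacua"), dir)
  bad <- utils::read.csv(system.file("extdata", "params", "rates_brca1.csv",
                                     package = "brcacua"))
  bad$rate[3] <- -0.1
  utils::write.csv(bad, file.path(dir, "rates_brca1.csv"), row.names = FALSE)
  expect_error(brca_parameters("BRCA1", dir = dir), "line 4")
})

test_that("configuration enforces the lifelong horizon and scenario ages", {
  cfg <- cua_config()
  expect_identical(cfg$n_cycles, 60L)
  expect_identical(cua_config(start_age = 30)$n_cycles, 70L)
  expect_error(cua_config(start_age = 40, n_cycles = 30), "age 100")
  expect_error(cua_config(disc_cost = -0.01), ">= 0")
  # WTP of CHF 100,000 converts to EUR at the fixed 1.10 rate
  expect_equal(wtp_value(cfg), 90909.0909, tolerance = 1e-6)
  expect_equal(wtp_value(cua_config(currency = "CHF")), 100000)
})
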
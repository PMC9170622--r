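test_that("strategy definitions load from the shipped data file", {
  ss <- strategy_set()
  expect_setequal(names(ss), STRATEGIES)
  expect_length(ss$IS$hr_effects, 0)
  expect_length(ss$IS$one_off, 0)
  expect_true(ss$PBM_PBSO$hrt)
  expect_setequal(unlist(ss$PBM_PBSO$hr_effects),
                  c("bc_incidence", "oc_incidence", "oc_incidence_prior_bc"))
})

test_that("effective rates apply the printed hazard ratios", {
  p1 <- brca_parameters("BRCA1")
  base <- list(df_bc = 0.0309, df_oc = 0.0220, bc_cbc = 0.0209,
               bc_oc = 0.0185, postoc_bc = 0.0144)
  expect_identical(effective_rates(base, "IS", p1), base)
  r <- effective_rates(base, "PBSO", p1)
  expect_equal(r$df_oc, 0.00616)                    # 0.0220 * 0.28
  expect_equal(r$bc_oc, 0.0185 * 0.14)              # prior-BC ratio replaces
  expect_identical(r$df_bc, base$df_bc)             # PBSO never affects BC
  r <- effective_rates(base, "PBM", p1)
  expect_equal(r$df_bc, 0.0309 * 0.09)
  expect_equal(r$postoc_bc, 0.0144 * 0.09)
  expect_identical(r$df_oc, base$df_oc)
  r <- effective_rates(base, "CP", p1)
  expect_equal(r$bc_cbc, 0.009196)                  # 0.0209 * 0.44
  expect_equal(r$df_bc, 0.0309 * (0.2 * 0.31 + 0.8))
  # BRCA2 uses its own contralateral ratio
  p2 <- brca_parameters("BRCA2")
  expect_equal(effective_rates(base, "CP", p2)$bc_cbc, 0.0209 * 0.33)
  # combined surgery applies both surgical effect sets
  r <- effective_rates(base, "PBM_PBSO", p1)
  expect_equal(r$df_bc, 0.0309 * 0.09)
  expect_equal(r$df_oc, 0.0220 * 0.28)
  expect_error(effective_rates(base, "XX", p1), "unknown strategy")
})

test_that("effective rates never exceed base rates for any strategy", {
  for (mut in c("BRCA1", "BRCA2")) {
    p <- brca_parameters(mut)
    base <- list(df_bc = 0.03, df_oc = 0.02, bc_cbc = 0.02, bc_oc = 0.0185,
                 postoc_bc = 0.0144)
    for (s in STRATEGIES) {
      r <- effective_rates(base, s, p)
      for (k in names(base)) expect_lte(r[[k]], base[[k]])
    }
  }
})

test_that("an inactive chemoprevention window restores base incidence", {
  p <- brca_parameters("BRCA1")
  base <- list(df_bc = 0.03, df_oc = 0.02, bc_cbc = 0.02, bc_oc = 0.0185,
               postoc_bc = 0.0144)
  expect_identical(effective_rates(base, "CP", p, cp_active = FALSE), base)
  # alternative reading of the chemoprevention figure as 1 - RRR
  r <- effective_rates(base, "CP", p, cp_interpretation = "one_minus_rrr")
  expect_equal(r$df_bc, 0.03 * (0.2 * 0.69 + 0.8))
})

test_that("strategy disutilities have the stated values and durations", {
  ut <- brca_parameters("BRCA1")$utilities
  cfg <- cua_config()
  expect_equal(strategy_utility_multiplier("PBM_PBSO", 0, 40, ut, cfg), 0.79)
  expect_equal(strategy_utility_multiplier("PBM_PBSO", 3, 43, ut, cfg), 1.0)
  expect_equal(strategy_utility_multiplier("CP", 4, 44, ut, cfg), 0.90)
  expect_equal(strategy_utility_multiplier("CP", 5, 45, ut, cfg), 1.0)
  expect_equal(strategy_utility_multiplier("PBM", 0, 40, ut, cfg), 0.88)
  expect_equal(strategy_utility_multiplier("PBSO", 0, 40, ut, cfg), 0.90)
  # surveillance decrement follows the imaging schedule by default
  expect_equal(strategy_utility_multiplier("IS", 25, 65, ut, cfg), 0.96)
  expect_equal(strategy_utility_multiplier("IS", 31, 71, ut, cfg), 1.0)
  expect_equal(strategy_utility_multiplier("IS", 32, 72, ut, cfg), 0.96)
  cfg1 <- cua_config(is_disutility = "first_year")
  expect_equal(strategy_utility_multiplier("IS", 0, 40, ut, cfg1), 0.96)
  expect_equal(strategy_utility_multiplier("IS", 25, 65, ut, cfg1), 1.0)
  # scenario: surgical decrement held for 10 years
  cfg10 <- cua_config(surgical_disutility_years = 10)
  expect_equal(strategy_utility_multiplier("PBM", 9, 49, ut, cfg10), 0.88)
  expect_equal(strategy_utility_multiplier("PBM", 10, 50, ut, cfg10), 1.0)
})

test_that("uptake blending is linear, order-independent and degenerate at
           unit weights", {
  fit <- cua("BRCA2", keep_traces = FALSE)
  tot <- fit$totals
  pure <- uptake_mix(fit, c(IS = 1))
  expect_equal(pure$cost, tot$cost[tot$strategy == "IS"])
  half <- uptake_mix(fit, c(IS = 0.5, PBM_PBSO = 0.5))
  expect_equal(half$qaly, mean(tot$qaly[tot$strategy %in% c("IS", "PBM_PBSO")]))
  a <- uptake_mix(fit, c(IS = 0.33, PBSO = 0.49, PBM = 0.18))
  b <- uptake_mix(fit, c(PBM = 0.18, IS = 0.33, PBSO = 0.49))
  expect_equal(a, b)
  i <- match(c("IS", "PBSO", "PBM"), tot$strategy)
  expect_equal(a$cost, sum(c(0.33, 0.49, 0.18) * tot$cost[i]))
  expect_error(uptake_mix(fit, c(IS = 0.5)), "sum to 1")
  expect_error(uptake_mix(fit, c(IS = 1.5, PBM = -0.5)), "non-negative")
})
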
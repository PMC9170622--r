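test_that("transition matrices are valid probability matrices with the
           diagram's structural zeros", {
  model <- base_model("BRCA1")
  for (cycle in c(0, 10, 35, 59)) {
    P <- build_transition_matrix(cycle, "PBM_PBSO", model)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(rowSums(P)), rep(1, 36), tolerance = 1e-12)
    # forbidden transitions
    expect_identical(unname(P["DF", "MBC"]), 0)             # MBC only after BC
    expect_identical(unname(P["MBC", "DF"]), 0)             # MBC is terminal
    expect_true(all(P["MBC", setdiff(colnames(P), c("MBC", "Dead"))] == 0))
    expect_true(all(P["OC_y3", grepl("^CBC", colnames(P))] == 0))
    expect_identical(unname(P["PostOC", "OC_y1"]), 0)       # no second OC
    expect_identical(unname(P["Dead", "Dead"]), 1)          # absorbing
    expect_true(all(P["Dead", -36] == 0))
  }
})

test_that("strategy effects compose into the disease-free row as printed", {
  model <- base_model("BRCA1")
  # age 41 = cycle 1: BC exit from band 41-50, OC from band 40-49
  P <- build_transition_matrix(1, "PBM_PBSO", model)
  rates <- c(bc = 0.0309 * 0.09, oc = 0.0155 * 0.28,
             dead = -log(1 - model$qx[2]))
  ct <- competing_transitions(rates)
  expect_equal(unname(P["DF", "BC_y1"]), unname(ct$p[["bc"]]), tolerance = 1e-12)
  expect_equal(unname(P["DF", "OC_y1"]), unname(ct$p[["oc"]]), tolerance = 1e-12)
  # metastatic row at age 45: cancer-specific plus background mortality
  P45 <- build_transition_matrix(5, "IS", model)
  r_dead <- 0.2033 - log(1 - model$qx[6])
  expect_equal(unname(P45["MBC", "Dead"]), 1 - exp(-r_dead), tolerance = 1e-12)
})

test_that("a disease-free cohort with no exits stays put and collects
           discounted life years", {
  p <- no_disease_params()
  model <- build_model("BRCA1", params = p, life_table = zero_life_table())
  tr <- run_cohort("IS", model)
  expect_equal(tr$occupancy[, "DF"], rep(1, 61), tolerance = 1e-12)
  out <- accumulate_outcomes(tr, model)
  expect_equal(out$ly, sum(1.03^-(0:59)), tolerance = 1e-9)
})

test_that("certain immediate death empties the cohort after one cycle", {
  p <- no_disease_params()
  model <- build_model("BRCA1", params = p, life_table = flat_life_table(1))
  tr <- run_cohort("IS", model)
  expect_equal(unname(tr$occupancy[2, "Dead"]), 1, tolerance = 1e-9)
  out <- accumulate_outcomes(tr, model)
  expect_equal(out$ly, 1, tolerance = 1e-6)  # one start-of-cycle year lived
})

test_that("degenerate two-state model matches the geometric closed form", {
  q <- 0.07
  p <- no_disease_params()
  model <- build_model("BRCA1", params = p, life_table = flat_life_table(q))
  out <- accumulate_outcomes(run_cohort("IS", model), model)
  t <- 0:59
  expect_equal(out$ly, sum(((1 - q) / 1.03)^t), tolerance = 1e-9)
})

test_that("occupancy is conserved and death is monotone on random
           parameterizations", {
  set.seed(7)
  for (i in 1:25) {
    model <- random_model(sample(c("BRCA1", "BRCA2"), 1))
    strat <- sample(STRATEGIES, 1)
    tr <- run_cohort(strat, model)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, model$n + 1),
                 tolerance = 1e-10)
    expect_true(all(diff(tr$occupancy[, "Dead"]) >= -1e-14))
  }
})

test_that("lowering an incidence rate never lowers total life years", {
  model <- base_model("BRCA1")
  base_ly <- accumulate_outcomes(run_cohort("IS", model), model)$ly
  for (tr_name in c("df_bc", "df_oc", "bc_mbc")) {
    m2 <- model
    i <- which(m2$params$rates$transition == tr_name)
    m2$params$rates$rate[i] <- m2$params$rates$rate[i] * 0.5
    m2 <- brcacua:::.rebuild_model(m2)
    pert_ly <- accumulate_outcomes(run_cohort("IS", m2), m2)$ly
    expect_gte(pert_ly, base_ly)
  }
})

test_that("a null strategy (all hazard ratios one, surveillance bindings)
           reproduces intensified surveillance bit for bit", {
  model <- base_model("BRCA1")
  model$params$hrs$hr[] <- 1.0
  model <- brcacua:::.rebuild_model(model)
  null_spec <- list(name = "IS",
                    hr_effects = list("bc_incidence", "oc_incidence",
                                      "oc_incidence_prior_bc", "cbc_incidence",
                                      "erpos_bc_incidence"),
                    disutility_mode = "surveillance", one_off = list(),
                    surveillance = "is_full", hrt = FALSE,
                    implant_lumps = FALSE, cp_drug = FALSE)
  out_null <- accumulate_outcomes(run_cohort(null_spec, model), model)
  out_is <- accumulate_outcomes(run_cohort("IS", model), model)
  expect_identical(out_null$cost, out_is$cost)
  expect_identical(out_null$qaly, out_is$qaly)
  expect_identical(out_null$ly, out_is$ly)
})

test_that("the cohort trace exports one row per cycle", {
  model <- base_model()
  tr <- run_cohort("IS", model)
  path <- withr::local_tempfile(fileext = ".csv")
  export_trace(tr, model, path)
  df <- utils::read.csv(path)
  expect_identical(nrow(df), model$n)
  expect_true(all(c("DF", "BC_y1", "Dead", "d_qaly") %in% names(df)))
})
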
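test_that("distribution fits match their first two moments", {
  # gamma by method of moments: Table-1-style rate with its SE
  g <- list(family = "gamma", central = 0.0209, se = 0.0025, support = c(0, Inf))
  shape <- 0.0209^2 / 0.0025^2
  expect_equal(shape, 69.9, tolerance = 0.01)
  expect_equal(0.0025^2 / 0.0209, 2.990e-4, tolerance = 1e-3)
  set.seed(1)
  x <- fit_distribution(g)(2e5)
  expect_equal(mean(x), 0.0209, tolerance = 0.01)
  expect_equal(stats::sd(x), 0.0025, tolerance = 0.02)
  # zero SE collapses to a point mass
  pt <- fit_distribution(list(family = "gamma", central = 0.5, se = 0))
  expect_identical(pt(10), rep(0.5, 10))
  # beta mean matches the utility central value
  b <- list(family = "beta", central = 0.96, se = 0.96 * 0.05 / 1.96)
  y <- fit_distribution(b)(2e5)
  expect_equal(mean(y), 0.96, tolerance = 0.005)
  expect_true(all(y > 0 & y < 1))
  # lognormal moments are matched on the natural scale
  l <- list(family = "lognormal", central = 0.28, se = 0.14)
  z <- fit_distribution(l)(2e5)
  expect_equal(mean(z), 0.28, tolerance = 0.01)
  expect_equal(stats::sd(z), 0.14, tolerance = 0.02)
  expect_error(fit_distribution(list(family = "beta", central = 0.5, se = 0.6)),
               "incompatible")
})

test_that("the uncertain-parameter set covers rates, ratios, utilities and
           costs with the prescribed families", {
  model <- base_model("BRCA1")
  ups <- uncertain_parameters(model)
  fam <- vapply(ups, `[[`, character(1), "family")
  ids <- vapply(ups, `[[`, character(1), "id")
  expect_true(all(fam[grepl("^hr:", ids)] == "lognormal"))
  expect_true(all(fam[grepl("^utility:", ids)] == "beta"))
  expect_true(all(fam[grepl("^cost:", ids)] == "gamma"))
  expect_true(all(fam[grepl("^rate:", ids)] %in% c("gamma", "uniform")))
  # the range-only rates sample uniformly over their published range
  expect_identical(fam[ids == "rate:bc_oc:0-inf"], "uniform")
  # a patched draw lands in the rebuilt model
  p <- ups[[which(ids == "hr:bc_incidence")]]
  m2 <- brcacua:::.rebuild_model(p$patch(model, 0.5))
  expect_equal(m2$params$hrs$hr[m2$params$hrs$effect == "bc_incidence"], 0.5)
})

test_that("utility variation can be read as CI half-range or direct SE", {
  model <- base_model("BRCA1")
  se1 <- vapply(uncertain_parameters(model), function(p)
    if (p$id == "utility:IS") p$se else NA_real_, numeric(1))
  se2 <- vapply(uncertain_parameters(model, util_var_mode = "direct_se"),
                function(p) if (p$id == "utility:IS") p$se else NA_real_,
                numeric(1))
  expect_equal(stats::na.omit(se1)[[1]], 0.96 * 0.05 / 1.96)
  expect_equal(stats::na.omit(se2)[[1]], 0.96 * 0.05)
})

test_that("PSA is reproducible and internally consistent", {
  fit <- cua("BRCA2", keep_traces = FALSE)
  p1 <- run_psa(fit, n = 15, seed = 99)
  p2 <- run_psa(fit, n = 15, seed = 99)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$qaly, p2$qaly)
  expect_identical(p1$draws, p2$draws)
  # acceptability probabilities are proper
  expect_true(all(p1$ceac >= 0 & p1$ceac <= 1))
  expect_equal(unname(rowSums(p1$ceac)), rep(1, nrow(p1$ceac)), tolerance = 1e-12)
  expect_equal(sum(p1$prob_optimal), 1)
  s <- summary(p1)
  expect_identical(nrow(s), 5L)
  expect_true(all(is.finite(s$qaly)))
  expect_error(run_psa(fit, n = 0, seed = 1), "positive")
})

test_that("tornado bars order by influence and degenerate parameters give
           zero width", {
  fit <- cua("BRCA1", keep_traces = FALSE)
  ups <- uncertain_parameters(fit)
  ids <- vapply(ups, `[[`, character(1), "id")
  pick <- ups[ids %in% c("rate:bc_oc:0-inf", "hr:oc_incidence",
                         "cost:one_off:pbso_surgery")]
  tw <- tornado(fit, "PBM_PBSO", "IS", params = pick)
  expect_identical(nrow(tw), 3L)
  expect_true(all(diff(tw$width) <= 0))
  # a parameter with zero spread cannot move the outcome
  frozen <- list(list(id = "frozen", family = "gamma", central = 0.0209,
                      se = 0, support = c(0, Inf),
                      patch = function(m, v) {
                        m$params$rates$rate[1] <- v; m
                      }))
  tw0 <- tornado(fit, "PBM_PBSO", "IS", params = frozen)
  expect_equal(tw0$width, 0)
})
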
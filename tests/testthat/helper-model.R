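# Shared fixtures for the test suite: small model builders and an
# individual-level microsimulation used as an independent oracle.

base_model <- function(mutation = "BRCA1", config = cua_config(), ...) {
  build_model(mutation, config = config, ...)
}

# A life table with zero mortality everywhere (for closed-form checks).
zero_life_table <- function() {
  df <- data.frame(age = 0:100, qx = 0)
  class(df) <- c("life_table", "data.frame")
  df
}

flat_life_table <- function(q) {
  df <- data.frame(age = 0:100, qx = q)
  class(df) <- c("life_table", "data.frame")
  df
}

# Parameters with every disease rate zeroed (general-population cohort).
no_disease_params <- function(mutation = "BRCA1") {
  p <- brca_parameters(mutation)
  p$rates$rate <- 0
  p
}

# Draw a random valid parameterization around the base inputs (used for
# property-style conservation tests).
random_model <- function(mutation = "BRCA1", config = cua_config()) {
  m <- build_model(mutation, config = config)
  ups <- uncertain_parameters(m)
  for (p in ups) m <- p$patch(m, fit_distribution(p)(1))
  brcacua:::.rebuild_model(m)
}

# Individual-level microsimulation with the same transition matrices and
# rewards as the cohort engine; returns means and standard errors of
# discounted LY/QALY per woman.
microsim <- function(model, strategy, n_women = 200000, seed = 1) {
  set.seed(seed)
  sp <- brcacua:::.strategy_spec(strategy, model$strategies)
  r <- brcacua:::.adjusted_rates(model, sp)
  P <- brcacua:::.transition_array(model, r)
  U <- brcacua:::.utility_matrix(model, sp)
  dead <- model$ss$dead
  state <- rep(1L, n_women)
  ly <- qaly <- numeric(n_women)
  for (t in seq_len(model$n)) {
    alive <- state != dead
    ly <- ly + model$disc_out[t] * alive
    qaly <- qaly + model$disc_out[t] * U[t, state]
    new_state <- state
    for (s in unique(state)) {
      if (s == dead) next
      idx <- which(state == s)
      new_state[idx] <- sample.int(36L, length(idx), replace = TRUE,
                                   prob = P[s, , t])
    }
    state <- new_state
  }
  list(ly = mean(ly), ly_se = stats::sd(ly) / sqrt(n_women),
       qaly = mean(qaly), qaly_se = stats::sd(qaly) / sqrt(n_women))
}

# Brute-force dominance oracle: absolute dominance by exhaustive pairwise
# comparison; extended dominance by the two-point interpolation (hull) test.
oracle_dominance <- function(res) {
  n <- nrow(res)
  lab <- rep("nondominated", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (res$cost[j] <= res$cost[i] && res$qaly[j] >= res$qaly[i] &&
        (res$cost[j] < res$cost[i] || res$qaly[j] > res$qaly[i]))
      lab[i] <- "absolutely_dominated"
  }
  for (i in which(lab == "nondominated")) {
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      if (lab[j] == "absolutely_dominated" || lab[k] == "absolutely_dominated") next
      qj <- res$qaly[j]; qk <- res$qaly[k]
      if (qj < res$qaly[i] && res$qaly[i] < qk) {
        lam <- (res$qaly[i] - qj) / (qk - qj)
        blend_cost <- (1 - lam) * res$cost[j] + lam * res$cost[k]
        if (blend_cost < res$cost[i]) lab[i] <- "extendedly_dominated"
      }
    }
  }
  for (i in seq_len(n)) {
    o <- setdiff(seq_len(n), i)
    if (all(res$cost[i] < res$cost[o]) && all(res$qaly[i] > res$qaly[o]))
      lab[i] <- "dominant"
  }
  stats::setNames(lab, res$strategy)
}
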
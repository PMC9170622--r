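# Markov cohort engine: assembles cycle-indexed transition matrices over the
# expanded tunnel-state space and runs the cohort trace.

#' Assemble a model bundle
#'
#' Precomputes everything the engine needs for one mutation: the expanded
#' state space, per-cycle ages and discount factors, per-cycle base transition
#' rates looked up from the age-banded tables, background mortality rates from
#' the life table, and the composed cost vectors.
#'
#' @param mutation `"BRCA1"` or `"BRCA2"`.
#' @param params [brca_parameters()]; defaults to the packaged set.
#' @param life_table A [read_life_table()] data frame; defaults to the
#'   bundled synthetic Swiss-like table.
#' @param costs A [read_cost_schedule()] schedule; defaults to the bundled
#'   synthetic fixture.
#' @param config A [cua_config()].
#' @param strategies A [strategy_set()].
#' @return Object of class `cua_model`.
#' @export
build_model <- function(mutation = MUTATIONS, params = NULL, life_table = NULL,
                        costs = NULL, config = cua_config(),
                        strategies = strategy_set()) {
  mutation <- match.arg(mutation)
  if (is.null(params)) params <- brca_parameters(mutation)
  if (is.null(life_table)) life_table <- swiss_life_table()
  if (is.null(costs)) costs <- default_cost_schedule()
  ss <- build_state_space()
  n <- config$n_cycles
  ages <- config$start_age + 0:(n - 1)
  qx <- .qx_at(life_table, ages)
  base <- list(
    df_bc = lookup_rate(params$rates, "df_bc", ages),
    df_oc = lookup_rate(params$rates, "df_oc", ages),
    bc_cbc = lookup_rate(params$rates, "bc_cbc", ages),
    bc_mbc = lookup_rate(params$rates, "bc_mbc", ages),
    bc_oc = lookup_rate(params$rates, "bc_oc", ages),
    postoc_bc = lookup_rate(params$rates, "postoc_bc", ages),
    bc_death = lookup_rate(params$rates, "bc_death", ages),
    mbc_death = lookup_rate(params$rates, "mbc_death", ages),
    oc_death = lookup_rate(params$rates, "oc_death", ages) *
      config$oc_mortality_multiplier,
    bg = -log(1 - pmin(qx, 1 - 1e-12)))
  ccur <- function(x) if (config$currency == "CHF")
    convert_currency(x, "EUR", "CHF", config$eur_chf) else x
  structure(list(
    mutation = mutation, params = params, life_table = life_table,
    costs = costs, config = config, strategies = strategies,
    ss = ss, n = n, ages = ages, qx = qx, base = base,
    disc_out = (1 + config$disc_outcomes)^-(0:(n - 1)),
    disc_cost = (1 + config$disc_cost)^-(0:(n - 1)),
    ccur = ccur), class = "cua_model")
}

#' @export
print.cua_model <- function(x, ...) {
  cat("Markov cohort model bundle:", x$mutation, "| start age",
      x$config$start_age, "|", x$n, "annual cycles\n")
  invisible(x)
}

# Per-cycle strategy-adjusted rates (each element a vector over cycles).
.adjusted_rates <- function(model, sp) {
  cfg <- model$config
  cp_active <- if (is.finite(cfg$tamoxifen_effect_years))
    (0:(model$n - 1)) < cfg$tamoxifen_effect_years else rep(TRUE, model$n)
  if (all(cp_active)) {
    effective_rates(model$base, sp, model$params, TRUE, cfg$cp_interpretation)
  } else {
    on  <- effective_rates(model$base, sp, model$params, TRUE, cfg$cp_interpretation)
    off <- effective_rates(model$base, sp, model$params, FALSE, cfg$cp_interpretation)
    lapply(stats::setNames(names(on), names(on)), function(k)
      ifelse(cp_active, on[[k]], off[[k]]))
  }
}

#' One-cycle transition matrix
#'
#' Builds the 36 x 36 transition-probability matrix for a given cycle under a
#' strategy. Within-cycle competing risks use the proportional-split
#' exponential formula, so every row sums to one exactly and transitions the
#' state diagram forbids are structural zeros.
#'
#' @param cycle Cycle index, 0-based (age = start_age + cycle).
#' @param strategy Strategy name or spec.
#' @param model A [build_model()] bundle.
#' @return Transition matrix with state-name dimnames.
#' @export
build_transition_matrix <- function(cycle, strategy, model) {
  sp <- .strategy_spec(strategy, model$strategies)
  r <- .adjusted_rates(model, sp)
  P <- .transition_array(model, r)[, , cycle + 1]
  dimnames(P) <- list(model$ss$names, model$ss$names)
  bad <- abs(rowSums(P) - 1) > 1e-12
  if (any(bad))
    stop("transition rows do not sum to 1 at cycle ", cycle, " for state(s) ",
         paste(model$ss$names[bad], collapse = ", "))
  P
}

# All per-cycle transition matrices as a 36 x 36 x n array.
.transition_array <- function(model, r) {
  n <- model$n
  cfg <- model$config
  bgc <- if (cfg$background_mortality_in_cancer) model$base$bg else rep(0, n)
  P <- array(0, dim = c(36, 36, n))
  iDF <- 1; iBC <- 2:11; iCBC <- 12:21; iMBC <- 22; iPBC <- 23; iPCBC <- 24
  iOC <- 25:34; iPOC <- 35; iD <- 36
  for (t in seq_len(n)) {
    # DF
    ct <- competing_transitions(c(bc = r$df_bc[t], oc = r$df_oc[t],
                                  dead = model$base$bg[t]))
    P[iDF, iBC[1], t] <- ct$p[["bc"]]; P[iDF, iOC[1], t] <- ct$p[["oc"]]
    P[iDF, iD, t] <- ct$p[["dead"]]; P[iDF, iDF, t] <- ct$stay
    # BC tunnel (exits shared across tunnel years)
    cb <- competing_transitions(c(cbc = r$bc_cbc[t], mbc = r$bc_mbc[t],
                                  oc = r$bc_oc[t],
                                  dead = model$base$bc_death[t] + bgc[t]))
    for (k in 1:10) {
      s <- iBC[k]
      P[s, iCBC[1], t] <- cb$p[["cbc"]]; P[s, iMBC, t] <- cb$p[["mbc"]]
      P[s, iOC[1], t] <- cb$p[["oc"]]; P[s, iD, t] <- cb$p[["dead"]]
      P[s, if (k < 10) iBC[k + 1] else iPBC, t] <- cb$stay
    }
    # CBC tunnel (no second contralateral event)
    cc <- competing_transitions(c(mbc = r$bc_mbc[t], oc = r$bc_oc[t],
                                  dead = model$base$bc_death[t] + bgc[t]))
    for (k in 1:10) {
      s <- iCBC[k]
      P[s, iMBC, t] <- cc$p[["mbc"]]; P[s, iOC[1], t] <- cc$p[["oc"]]
      P[s, iD, t] <- cc$p[["dead"]]
      P[s, if (k < 10) iCBC[k + 1] else iPCBC, t] <- cc$stay
    }
    # MBC
    cm <- competing_transitions(c(dead = model$base$mbc_death[t] + bgc[t]))
    P[iMBC, iD, t] <- cm$p[["dead"]]; P[iMBC, iMBC, t] <- cm$stay
    # Post-BC (age-adjusted mortality only)
    cp1 <- competing_transitions(c(cbc = r$bc_cbc[t], mbc = r$bc_mbc[t],
                                   oc = r$bc_oc[t], dead = model$base$bg[t]))
    P[iPBC, iCBC[1], t] <- cp1$p[["cbc"]]; P[iPBC, iMBC, t] <- cp1$p[["mbc"]]
    P[iPBC, iOC[1], t] <- cp1$p[["oc"]]; P[iPBC, iD, t] <- cp1$p[["dead"]]
    P[iPBC, iPBC, t] <- cp1$stay
    # Post-CBC
    cp2 <- competing_transitions(c(mbc = r$bc_mbc[t], oc = r$bc_oc[t],
                                   dead = model$base$bg[t]))
    P[iPCBC, iMBC, t] <- cp2$p[["mbc"]]; P[iPCBC, iOC[1], t] <- cp2$p[["oc"]]
    P[iPCBC, iD, t] <- cp2$p[["dead"]]; P[iPCBC, iPCBC, t] <- cp2$stay
    # OC tunnel
    co <- competing_transitions(c(dead = model$base$oc_death[t] + bgc[t]))
    for (k in 1:10) {
      s <- iOC[k]
      P[s, iD, t] <- co$p[["dead"]]
      P[s, if (k < 10) iOC[k + 1] else iPOC, t] <- co$stay
    }
    # Post-OC (metachronous breast cancer re-entry)
    cpo <- competing_transitions(c(bc = r$postoc_bc[t], dead = model$base$bg[t]))
    P[iPOC, iBC[1], t] <- cpo$p[["bc"]]; P[iPOC, iD, t] <- cpo$p[["dead"]]
    P[iPOC, iPOC, t] <- cpo$stay
    # Dead absorbing
    P[iD, iD, t] <- 1
  }
  P
}

#' Run the cohort trace
#'
#' Starts the whole cohort disease-free at the starting age and applies the
#' cycle-indexed transition matrices sequentially, recording per-cycle
#' occupancy, the mass entering each aggregate state, and the mass flowing
#' from each state to dead (needed for palliative lump sums).
#'
#' @param strategy Strategy name or spec.
#' @param model A [build_model()] bundle.
#' @return Object of class `cohort_trace` with `occupancy`
#'   ((n_cycles + 1) x 36), `death_flows` (n_cycles x 36), `entry_flows`
#'   (n_cycles x aggregate states) and the strategy name.
#' @export
run_cohort <- function(strategy, model) {
  sp <- .strategy_spec(strategy, model$strategies)
  r <- .adjusted_rates(model, sp)
  P <- .transition_array(model, r)
  n <- model$n
  ss <- model$ss
  occ <- matrix(0, n + 1, 36, dimnames = list(NULL, ss$names))
  occ[1, 1] <- 1
  death_flows <- matrix(0, n, 36, dimnames = list(NULL, ss$names))
  aggs <- unique(unname(ss$aggregate))
  entry <- matrix(0, n, length(aggs), dimnames = list(NULL, aggs))
  agg_of <- unname(ss$aggregate)
  for (t in seq_len(n)) {
    Pt <- P[, , t]
    rs <- rowSums(Pt)
    if (any(abs(rs - 1) > 1e-12))
      stop("transition rows do not sum to 1 at cycle ", t - 1, " for state(s) ",
           paste(ss$names[abs(rs - 1) > 1e-12], collapse = ", "))
    v <- occ[t, ]
    occ[t + 1, ] <- v %*% Pt
    death_flows[t, ] <- v * Pt[, ss$dead]
    # mass entering each aggregate state from a different aggregate state
    flow <- v * Pt  # flow[i, j]
    for (a in aggs) {
      ja <- which(agg_of == a)
      entry[t, a] <- sum(flow[agg_of != a, ja])
    }
  }
  structure(list(occupancy = occ, death_flows = death_flows,
                 entry_flows = entry, strategy = sp$name),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat("Cohort trace:", x$strategy, "|", n, "cycles | final dead fraction",
      sprintf("%.4f", x$occupancy[n + 1, "Dead"]), "\n")
  invisible(x)
}

# Per-cycle utility matrix U[n, 36] for a strategy.
.utility_matrix <- function(model, sp) {
  ut <- model$params$utilities
  n <- model$n
  ages <- model$ages
  u_age <- df_utility(ut, ages)
  smult <- strategy_utility_multiplier(sp, 0:(n - 1), ages, ut, model$config)
  U <- matrix(0, n, 36, dimnames = list(NULL, model$ss$names))
  U[, "DF"] <- u_age * smult
  m_bc <- .recovery_multiplier(ut$state[["BC"]], 1:10)
  m_oc <- .recovery_multiplier(ut$state[["OC"]], 1:10)
  for (k in 1:10) {
    U[, paste0("BC_y", k)] <- u_age * m_bc[k]
    U[, paste0("CBC_y", k)] <- u_age * m_bc[k]
    U[, paste0("OC_y", k)] <- u_age * m_oc[k]
  }
  U[, "MBC"] <- u_age * ut$state[["MBC"]]
  U[, "PostBC"] <- u_age
  U[, "PostCBC"] <- u_age
  U[, "PostOC"] <- u_age
  U
}

# Per-cycle per-state annual cost matrix C[n, 36] (EUR; converted later).
.cost_matrix <- function(model, sp) {
  sc <- model$costs
  cfg <- model$config
  n <- model$n
  ages <- model$ages
  C <- matrix(0, n, 36, dimnames = list(NULL, model$ss$names))
  C[, "DF"] <- vapply(seq_len(n), function(t)
    .df_recurring(sc, sp, ages[t], t - 1, cfg), numeric(1))
  bc_y <- bc_year_costs(sc, model$params$mix, cfg, pbm_arm = isTRUE(sp$implant_lumps))
  oc_y <- oc_year_costs(sc, cfg)
  for (k in 1:10) {
    C[, paste0("BC_y", k)] <- bc_y[k]
    C[, paste0("CBC_y", k)] <- bc_y[k]
    C[, paste0("OC_y", k)] <- oc_y[k]
  }
  C[, "MBC"] <- mbc_annual_cost(sc, model$params$mix)
  C[, "PostBC"] <- vapply(ages, function(a) .post_bc_recurring(sc, sp, a, cfg), numeric(1))
  C[, "PostCBC"] <- C[, "PostBC"]
  C[, "PostOC"] <- vapply(ages, function(a) .post_oc_recurring(sc, sp, a), numeric(1))
  C
}

#' Accumulate discounted outcomes over a cohort trace
#'
#' Life years count occupancy of any alive state; QALYs weight occupancy by
#' the age-adjusted state utility (including the strategy disutility);
#' costs combine occupancy-weighted state-year and surveillance costs, the
#' cycle-0 one-off intervention, implant-replacement lump sums (every 10
#' years to age 70 after prophylactic mastectomy), and palliative lump sums
#' on transitions from cancer states to dead. Each cycle-t increment is
#' discounted by (1 + d)^-t, cycle 0 undiscounted.
#'
#' @param trace A [run_cohort()] trace.
#' @param model The [build_model()] bundle used to produce it.
#' @return List of class `cua_outcomes`: totals (`cost`, `qaly`, `ly`, and
#'   undiscounted counterparts) plus the per-cycle increment data frame.
#' @export
accumulate_outcomes <- function(trace, model) {
  sp <- .strategy_spec(trace$strategy, model$strategies)
  cfg <- model$config
  n <- model$n
  ss <- model$ss
  occ <- trace$occupancy[seq_len(n), , drop = FALSE]
  if (cfg$half_cycle)
    occ <- (occ + trace$occupancy[2:(n + 1), , drop = FALSE]) / 2
  alive <- ss$names != "Dead"
  U <- .utility_matrix(model, sp)
  C <- .cost_matrix(model, sp)
  ly_t <- rowSums(occ[, alive, drop = FALSE])
  qaly_t <- rowSums(occ * U)
  cost_t <- rowSums(occ * C)
  # palliative lump sums on cancer-state -> dead flows
  pall_states <- ss$aggregate[ss$names] %in% c("BC", "CBC", "MBC", "OC")
  cost_t <- cost_t + model$costs$palliative$lump *
    rowSums(trace$death_flows[, pall_states, drop = FALSE])
  # one-off prophylactic intervention at cycle 0 (undiscounted by convention)
  cost_t[1] <- cost_t[1] + .strategy_one_off(model$costs, sp)
  # implant replacement lumps after prophylactic mastectomy
  if (isTRUE(sp$implant_lumps)) {
    amt <- model$costs$assumptions$implant_share *
      model$costs$annuity$implant_replacement
    if (cfg$implant_mode == "lump") {
      due <- which((seq_len(n) - 1) %% 10 == 0 & (seq_len(n) - 1) > 0 &
                     model$ages <= 70)
      cost_t[due] <- cost_t[due] + amt * ly_t[due]
    } else {
      due <- which(model$ages < 70)
      cost_t[due] <- cost_t[due] + amt / 10 * ly_t[due]
    }
  }
  cost_t <- model$ccur(cost_t)
  inc <- data.frame(cycle = 0:(n - 1), age = model$ages,
                    ly = ly_t, qaly = qaly_t, cost = cost_t,
                    d_ly = ly_t * model$disc_out,
                    d_qaly = qaly_t * model$disc_out,
                    d_cost = cost_t * model$disc_cost)
  structure(list(strategy = sp$name,
                 cost = sum(inc$d_cost), qaly = sum(inc$d_qaly),
                 ly = sum(inc$d_ly),
                 cost_undisc = sum(inc$cost), qaly_undisc = sum(inc$qaly),
                 ly_undisc = sum(inc$ly), increments = inc),
            class = "cua_outcomes")
}

#' @export
print.cua_outcomes <- function(x, ...) {
  cat(sprintf("%s: discounted cost %.0f, QALYs %.2f, LYs %.2f\n",
              x$strategy, x$cost, x$qaly, x$ly))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle: occupancy of each expanded state plus discounted
#' per-cycle increments.
#'
#' @param trace A `cohort_trace`.
#' @param model The model bundle.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, model, path) {
  out <- accumulate_outcomes(trace, model)
  df <- cbind(as.data.frame(trace$occupancy[seq_len(model$n), , drop = FALSE]),
              out$increments[, c("d_ly", "d_qaly", "d_cost")])
  df <- cbind(cycle = 0:(model$n - 1), df)
  utils::write.csv(format(df, digits = NULL, nsmall = 6), path, row.names = FALSE)
  invisible(path)
}
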
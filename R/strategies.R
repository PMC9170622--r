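#' Strategy definitions
#'
#' The five risk-reducing strategies are declarative specifications shipped
#' as a data file (`inst/extdata/strategies.yaml`): which hazard-ratio
#' effects apply, the disutility mode, and the cost bindings (one-off
#' surgeries, surveillance profile, hormone replacement, implant
#' replacement, chemoprevention drug). Editing the file changes strategy
#' behaviour without code changes.
#'
#' @param path Optional alternative strategies file.
#' @return Named list of strategy specs, class `strategy_set`.
#' @export
strategy_set <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "strategies.yaml", package = "brcacua")
  ss <- yaml::read_yaml(path)
  for (nm in names(ss)) ss[[nm]]$name <- nm
  structure(ss, class = "strategy_set")
}

.strategy_spec <- function(strategy, set = NULL) {
  if (is.list(strategy)) return(strategy)
  if (is.null(set)) set <- strategy_set()
  sp <- set[[strategy]]
  if (is.null(sp)) stop("unknown strategy: ", strategy)
  sp
}

.hr_value <- function(hrs, effect) {
  i <- which(hrs$effect == effect)
  if (!length(i)) stop("no hazard ratio for effect '", effect, "'")
  hrs$hr[i[1]]
}

#' Strategy-adjusted transition rates
#'
#' Applies the strategy's hazard-ratio effects to the base incidence rates:
#' prophylactic mastectomy multiplies breast-cancer incidence (including
#' re-entry after ovarian cancer) by its hazard ratio; oophorectomy
#' multiplies ovarian-cancer incidence, with a stronger effect given prior
#' breast cancer that replaces the disease-free-state ratio; chemoprevention
#' reduces the HR+ fraction of breast-cancer incidence and applies a
#' mutation-specific contralateral effect. Oophorectomy never modifies
#' breast-cancer incidence.
#'
#' @param base_rates Named list/vector with elements `df_bc`, `df_oc`,
#'   `bc_cbc`, `bc_oc`, `postoc_bc` (annual rates).
#' @param strategy Strategy name or spec from [strategy_set()].
#' @param params [brca_parameters()] object (hazard ratios + subtype mix).
#' @param cp_active Is chemoprevention's effect active this cycle? (`FALSE`
#'   after the effect window in the 5-year-effect scenario.)
#' @param cp_interpretation See [cua_config()].
#' @return Named list of adjusted rates.
#' @export
effective_rates <- function(base_rates, strategy, params, cp_active = TRUE,
                            cp_interpretation = "hr") {
  sp <- .strategy_spec(strategy)
  r <- as.list(base_rates)
  hrs <- params$hrs
  eff <- sp$hr_effects
  if ("bc_incidence" %in% eff) {
    hr <- .hr_value(hrs, "bc_incidence")
    r$df_bc <- apply_hazard_ratio(r$df_bc, hr)
    r$postoc_bc <- apply_hazard_ratio(r$postoc_bc, hr)
  }
  if ("oc_incidence" %in% eff)
    r$df_oc <- apply_hazard_ratio(r$df_oc, .hr_value(hrs, "oc_incidence"))
  if ("oc_incidence_prior_bc" %in% eff)
    r$bc_oc <- apply_hazard_ratio(r$bc_oc, .hr_value(hrs, "oc_incidence_prior_bc"))
  if (cp_active) {
    if ("erpos_bc_incidence" %in% eff) {
      hr <- .hr_value(hrs, "erpos_bc_incidence")
      if (cp_interpretation == "one_minus_rrr") hr <- 1 - hr
      r$df_bc <- cp_effective_bc_rate(r$df_bc, params$mix, hr)
    }
    if ("cbc_incidence" %in% eff)
      r$bc_cbc <- apply_hazard_ratio(r$bc_cbc, .hr_value(hrs, "cbc_incidence"))
  }
  r
}

#' Strategy utility multiplier in the disease-free state
#'
#' Surgical strategies carry their disutility for
#' `config$surgical_disutility_years` cycles from the cycle-0 surgery
#' (1 year in the base case; held constant in the 5/10-year scenarios).
#' Chemoprevention carries its decrement for five years. Intensified
#' surveillance carries 0.96 in every cycle with scheduled imaging (or in
#' cycle 0 only, per `config$is_disutility`).
#'
#' @param strategy Strategy name or spec.
#' @param cycle Cycle index (0-based).
#' @param age Age at the cycle (used for the imaging schedule).
#' @param utilities The `utilities` element of [brca_parameters()].
#' @param config A [cua_config()].
#' @return Multiplier in [0, 1].
#' @export
strategy_utility_multiplier <- function(strategy, cycle, age, utilities, config) {
  sp <- .strategy_spec(strategy)
  u <- utilities$strategy[[sp$name]]
  switch(sp$disutility_mode,
    surveillance = if (config$is_disutility == "schedule") {
      ifelse(.imaging_year(age), u, 1)
    } else ifelse(cycle == 0, u, 1),
    five_year = ifelse(cycle < 5, u, 1),
    surgical = ifelse(cycle < config$surgical_disutility_years, u, 1),
    stop("unknown disutility mode: ", sp$disutility_mode))
}

#' Blend strategy results by uptake weights
#'
#' Cost, QALY and LY totals of a mixed-uptake cohort are the weighted means
#' of the per-strategy totals (the model is linear in cohort composition).
#'
#' @param results Either a `cua_fit` or its `$totals` data frame.
#' @param weights Named non-negative weights over strategies, summing to 1.
#' @return One-row data frame with blended `cost`, `qaly`, `ly`.
#' @export
uptake_mix <- function(results, weights) {
  if (inherits(results, "cua_fit")) results <- results$totals
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  i <- match(names(weights), results$strategy)
  if (anyNA(i)) stop("unknown strategy in weights: ",
                     paste(names(weights)[is.na(i)], collapse = ", "))
  data.frame(cost = sum(weights * results$cost[i]),
             qaly = sum(weights * results$qaly[i]),
             ly = sum(weights * results$ly[i]))
}
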
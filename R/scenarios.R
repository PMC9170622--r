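# Scenario analyses as declarative overrides of the base configuration.

#' The model's scenario definitions
#'
#' Each scenario is a named list of configuration overrides: earlier start
#' ages (30/35), longer surgical disutility (5/10 years, held constant),
#' a 5-year chemoprevention effect, ovarian-cancer mortality reduced by 30%,
#' and deferred breast reconstruction. Anything not overridden keeps its
#' base-case value; the horizon auto-extends so it still reaches age 100.
#'
#' @return Named list of scenario specs.
#' @export
scenario_specs <- function() {
  list(
    base = list(),
    start_age_30 = list(start_age = 30),
    start_age_35 = list(start_age = 35),
    disutility_5 = list(surgical_disutility_years = 5),
    disutility_10 = list(surgical_disutility_years = 10),
    tamoxifen_5y = list(tamoxifen_effect_years = 5),
    oc_mortality_minus30 = list(oc_mortality_multiplier = 0.70),
    reconstruction_later = list(reconstruction_timing = "later")
  )
}

#' Apply a scenario to a configuration
#'
#' @param config A [cua_config()].
#' @param scenario A scenario name from [scenario_specs()] or a named list
#'   of overrides.
#' @return A new `cua_config` with the overrides applied; with no overrides
#'   the configuration is returned unchanged.
#' @export
apply_scenario <- function(config, scenario) {
  if (is.character(scenario)) {
    specs <- scenario_specs()
    if (!scenario %in% names(specs)) stop("unknown scenario: ", scenario)
    scenario <- specs[[scenario]]
  }
  if (!length(scenario)) return(config)
  bad <- setdiff(names(scenario), names(config))
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  args <- unclass(config)
  # cua_config() recomputes dependent fields and re-validates
  args[names(scenario)] <- scenario
  if ("start_age" %in% names(scenario) && !"n_cycles" %in% names(scenario))
    args$n_cycles <- NULL
  args$cycle_length <- NULL
  do.call(cua_config, args)
}

#' Run every scenario for one mutation
#'
#' @param mutation `"BRCA1"` or `"BRCA2"`.
#' @param scenarios Character vector of scenario names.
#' @param ... Passed to [cua()].
#' @return Named list of `cua_fit` objects.
#' @export
run_scenarios <- function(mutation, scenarios = names(scenario_specs()), ...) {
  out <- lapply(scenarios, function(s) cua(mutation, scenario = s,
                                           keep_traces = FALSE, ...))
  names(out) <- scenarios
  out
}
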
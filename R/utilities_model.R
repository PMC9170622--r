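#' Age-specific disease-free utility
#'
#' @param utilities The `utilities` element of [brca_parameters()].
#' @param age Age in years (vectorised).
#' @return Baseline utility of a disease-free woman at `age`.
#' @export
df_utility <- function(utilities, age) {
  tab <- utilities$df_age
  tab$value[.band_index(tab, age, "disease-free utilities")]
}

# Linear recovery multiplier: m(1) = u_d, rising linearly to 1 at year 6;
# constant 1 from year 6 on.
.recovery_multiplier <- function(u_d, tunnel_year) {
  ifelse(tunnel_year >= 6, 1, u_d + (1 - u_d) * (tunnel_year - 1) / 5)
}

#' Age-adjusted utility of an expanded state
#'
#' Utilities are age-adjusted by the multiplicative method: the age-specific
#' disease-free utility is multiplied by a state multiplier. Cancer states
#' carry the disease multiplier in the first year after diagnosis, recovering
#' linearly to the age-adjusted disease-free value by year 6; metastatic
#' disease keeps its multiplier until death; post-cancer states and tunnel
#' years 6-10 use the plain age-specific value; dead is 0.
#'
#' @param state Aggregate state (`"DF"`, `"BC"`, `"CBC"`, `"MBC"`, `"OC"`,
#'   `"PostBC"`, `"PostCBC"`, `"PostOC"`, `"Dead"`).
#' @param age Age in years.
#' @param tunnel_year Years since diagnosis (1-10) for cancer states.
#' @param utilities The `utilities` element of [brca_parameters()].
#' @param strategy_multiplier Multiplier applied in the disease-free state
#'   (strategy disutility), default 1.
#' @return Utility in [0, 1].
#' @export
age_adjusted_utility <- function(state, age, tunnel_year = NA,
                                 utilities, strategy_multiplier = 1) {
  if (state == "Dead") return(0)
  u <- df_utility(utilities, age)
  switch(state,
    DF = u * strategy_multiplier,
    BC = ,
    CBC = u * .recovery_multiplier(utilities$state[["BC"]], tunnel_year),
    OC = u * .recovery_multiplier(utilities$state[["OC"]], tunnel_year),
    MBC = u * utilities$state[["MBC"]],
    PostBC = ,
    PostCBC = ,
    PostOC = u,
    stop("unknown state: ", state))
}

#' Average ovarian-cancer utility from yearly components
#'
#' The constant ovarian-cancer utility is the arithmetic mean of five yearly
#' utilities spanning diagnosis, recurrence and end-stage disease.
#'
#' @param components Numeric vector of exactly five yearly utilities.
#' @return Their arithmetic mean.
#' @export
oc_utility_constant <- function(components) {
  if (length(components) != 5) stop("exactly 5 yearly utility components required")
  mean(components)
}
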
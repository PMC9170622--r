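#' Build the expanded tunnel-state space
#'
#' The nine aggregate health states (disease-free, breast cancer, contralateral
#' breast cancer, metastatic breast cancer, the three post-cancer states,
#' ovarian cancer, dead) are unrolled into 36 expanded states: the BC, CBC and
#' OC states become 10-year tunnels tracking time since diagnosis, so that
#' cancer-specific mortality, recovery of utility and year-specific treatment
#' costs can depend on years since diagnosis.
#'
#' @return Object of class `state_space` with elements `names` (36 state
#'   labels), `aggregate` (aggregate state per expanded state), `tunnel_year`
#'   (1-10 inside a tunnel, `NA` elsewhere) and the index of the dead state.
#' @export
build_state_space <- function() {
  nm <- c("DF",
          paste0("BC_y", 1:10),
          paste0("CBC_y", 1:10),
          "MBC", "PostBC", "PostCBC",
          paste0("OC_y", 1:10),
          "PostOC", "Dead")
  agg <- c("DF", rep("BC", 10), rep("CBC", 10), "MBC", "PostBC", "PostCBC",
           rep("OC", 10), "PostOC", "Dead")
  tun <- c(NA, 1:10, 1:10, NA, NA, NA, 1:10, NA, NA)
  structure(list(names = nm, n = length(nm),
                 aggregate = stats::setNames(agg, nm),
                 tunnel_year = stats::setNames(tun, nm),
                 dead = which(nm == "Dead")),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("Expanded state space:", x$n, "states over",
      length(unique(x$aggregate)), "aggregate health states\n")
  invisible(x)
}

# index helper
.si <- function(ss, name) match(name, ss$names)

#' Distribute competing event rates over one cycle
#'
#' With total exit rate R = sum(rates), each event receives probability
#' (rate/R) * (1 - exp(-R * dt)) and the stay probability is exp(-R * dt),
#' so the probabilities sum to one exactly and are independent of the order
#' in which events are listed.
#'
#' @param rates Named non-negative numeric vector of competing event rates
#'   (events/person-year); may be empty.
#' @param dt Cycle length in years.
#' @return List with `p` (named event probabilities) and `stay`.
#' @export
competing_transitions <- function(rates, dt = 1) {
  if (length(rates) && any(rates < 0)) stop("rates must be non-negative")
  R <- sum(rates)
  if (R <= 0) return(list(p = rates * 0, stay = 1))
  total <- 1 - exp(-R * dt)
  list(p = rates / R * total, stay = exp(-R * dt))
}
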
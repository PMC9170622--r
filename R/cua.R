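#' Cost-utility analysis of risk-reducing strategies
#'
#' Runs the Markov cohort model for one mutation under every requested
#' strategy and assembles the comparative league table: discounted lifetime
#' costs, QALYs and life years per strategy, differences against intensified
#' surveillance, ICERs or dominance labels.
#'
#' @param mutation `"BRCA1"` or `"BRCA2"`.
#' @param strategies Character vector of strategies to compare.
#' @param params [brca_parameters()] (defaults to the packaged printed inputs).
#' @param life_table [read_life_table()] table (defaults to the bundled
#'   synthetic fixture).
#' @param costs [read_cost_schedule()] schedule (defaults to the bundled
#'   synthetic fixture).
#' @param config A [cua_config()].
#' @param scenario Optional scenario name (see [scenario_specs()]) or a
#'   scenario spec; applied to the configuration before running.
#' @param keep_traces Keep the per-strategy cohort traces in the result.
#' @return Object of class `cua_fit` with elements `totals` (per-strategy
#'   discounted totals), `league` (the league table), `traces`, `model` per
#'   strategy inputs, and the fixture watermark.
#' @examples
#' fit <- cua("BRCA1")
#' fit
#' summary(fit)
#' @export
cua <- function(mutation = MUTATIONS, strategies = STRATEGIES,
                params = NULL, life_table = NULL, costs = NULL,
                config = cua_config(), scenario = NULL,
                keep_traces = TRUE) {
  mutation <- match.arg(mutation)
  strategies <- match.arg(strategies, STRATEGIES, several.ok = TRUE)
  if (!is.null(scenario)) config <- apply_scenario(config, scenario)
  model <- build_model(mutation, params = params, life_table = life_table,
                       costs = costs, config = config)
  traces <- lapply(strategies, run_cohort, model = model)
  names(traces) <- strategies
  outs <- lapply(traces, accumulate_outcomes, model = model)
  totals <- data.frame(
    strategy = strategies,
    cost = vapply(outs, `[[`, numeric(1), "cost"),
    qaly = vapply(outs, `[[`, numeric(1), "qaly"),
    ly = vapply(outs, `[[`, numeric(1), "ly"),
    cost_undisc = vapply(outs, `[[`, numeric(1), "cost_undisc"),
    qaly_undisc = vapply(outs, `[[`, numeric(1), "qaly_undisc"),
    ly_undisc = vapply(outs, `[[`, numeric(1), "ly_undisc"),
    row.names = NULL)
  lt <- if (length(strategies) > 1 && "IS" %in% strategies)
    league_table(totals) else NULL
  structure(list(mutation = mutation, totals = totals, league = lt,
                 traces = if (keep_traces) traces else NULL,
                 outcomes = outs, model = model, config = model$config,
                 watermark = model$costs$watermark %||% NULL),
            class = "cua_fit")
}

#' @export
print.cua_fit <- function(x, ...) {
  cat("Cost-utility analysis:", x$mutation, "| start age",
      x$config$start_age, "| discount",
      sprintf("%.0f%%", 100 * x$config$disc_cost), "|", x$config$currency, "\n")
  if (!is.null(x$watermark)) cat("NOTE:", x$watermark, "\n")
  if (!is.null(x$league)) print(x$league)
  else print(x$totals)
  invisible(x)
}

#' @export
summary.cua_fit <- function(object, ...) {
  wtp <- wtp_value(object$config)
  nmb <- net_monetary_benefit(object$totals, wtp)
  s <- list(fit = object, wtp = wtp,
            nmb = stats::setNames(nmb, object$totals$strategy),
            best = object$totals$strategy[which.max(nmb)])
  class(s) <- "summary.cua_fit"
  s
}

#' @export
print.summary.cua_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nWillingness-to-pay: %.2f %s per QALY\n",
              x$wtp, x$fit$config$currency))
  cat("Net monetary benefit by strategy:\n")
  for (s in names(sort(x$nmb, decreasing = TRUE)))
    cat(sprintf("  %-9s %12.0f\n", s, x$nmb[[s]]))
  cat("Highest net benefit:", x$best, "\n")
  invisible(x)
}

#' @export
coef.cua_fit <- function(object, ...) {
  m <- as.matrix(object$totals[, c("cost", "qaly", "ly")])
  rownames(m) <- object$totals$strategy
  m
}

#' Cost-effectiveness plane of the base-case results
#'
#' Plots incremental QALYs (vs the reference strategy) against incremental
#' costs for every strategy.
#'
#' @param x A `cua_fit`.
#' @param reference Reference strategy.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cua_fit <- function(x, reference = "IS", ...) {
  ref <- x$totals[x$totals$strategy == reference, ]
  dq <- x$totals$qaly - ref$qaly
  dc <- x$totals$cost - ref$cost
  graphics::plot(dq, dc, pch = 19,
                 xlab = "Incremental QALYs vs reference",
                 ylab = paste0("Incremental cost (", x$config$currency, ")"),
                 main = paste("Cost-effectiveness plane,", x$mutation), ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::abline(0, wtp_value(x$config), lty = 2, col = "grey40")
  graphics::text(dq, dc, x$totals$strategy, pos = 3, cex = 0.8)
  invisible(x)
}

#' Probabilistic sensitivity analysis via `simulate`
#'
#' `simulate` on a fitted analysis re-runs the model `nsim` times with all
#' uncertain parameters drawn jointly from their assigned distributions
#' (gamma for rates and costs, lognormal for hazard ratios, beta for
#' utilities); see [run_psa()].
#'
#' @param object A `cua_fit`.
#' @param nsim Number of iterations (10,000 in the full analysis).
#' @param seed Integer seed; required for reproducibility.
#' @param ... Passed to [run_psa()].
#' @return A `cua_psa` object.
#' @export
simulate.cua_fit <- function(object, nsim = 10000, seed = NULL, ...) {
  run_psa(object, n = nsim, seed = seed, ...)
}

#' Export the league table as CSV
#'
#' @param fit A `cua_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_league_table <- function(fit, path) {
  df <- as.data.frame(fit$league)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
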
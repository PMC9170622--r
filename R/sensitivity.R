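# One-way (tornado) and probabilistic sensitivity analysis.

#' Enumerate the model's uncertain parameters
#'
#' Builds the sampling plan for sensitivity analysis: gamma distributions
#' for rates and costs, lognormal for hazard ratios, beta for utilities;
#' parameters published only as a min-max range sample uniformly over it.
#' Utility variations given as "+/- X%" are interpreted as the half-width of
#' a 95% interval (SE = half-range / 1.96) unless `util_var_mode` is
#' `"direct_se"`.
#'
#' @param model A [build_model()] bundle (or a `cua_fit`).
#' @param cost_se_frac Relative SE assigned to every fixture cost anchor.
#' @param util_var_mode `"ci_half_range"` (default) or `"direct_se"`.
#' @return List of parameter descriptors (id, family, central, spread and a
#'   patch closure), class `uncertain_set`.
#' @export
uncertain_parameters <- function(model, cost_se_frac = 0.2,
                                 util_var_mode = c("ci_half_range", "direct_se")) {
  if (inherits(model, "cua_fit")) model <- model$model
  util_var_mode <- match.arg(util_var_mode)
  out <- list()
  add <- function(p) out[[length(out) + 1]] <<- p
  rates <- model$params$rates
  for (i in seq_len(nrow(rates))) {
    row <- rates[i, ]
    id <- sprintf("rate:%s:%s-%s", row$transition, row$age_lo,
                  ifelse(is.finite(row$age_hi), row$age_hi, "inf"))
    if (!is.na(row$lo) && !is.na(row$hi)) {
      add(list(id = id, family = "uniform", central = row$rate,
               lo = row$lo, hi = row$hi, se = (row$hi - row$lo) / 4,
               support = c(0, Inf),
               patch = local({ii <- i; function(m, v) {m$params$rates$rate[ii] <- v; m}})))
    } else if (!is.na(row$se) && row$se > 0) {
      add(list(id = id, family = "gamma", central = row$rate, se = row$se,
               support = c(0, Inf),
               patch = local({ii <- i; function(m, v) {m$params$rates$rate[ii] <- v; m}})))
    }
  }
  hrs <- model$params$hrs
  for (i in seq_len(nrow(hrs))) {
    if (is.na(hrs$se[i]) || hrs$se[i] <= 0) next
    add(list(id = paste0("hr:", hrs$effect[i]), family = "lognormal",
             central = hrs$hr[i], se = hrs$se[i], support = c(0, 1),
             patch = local({ii <- i; function(m, v) {m$params$hrs$hr[ii] <- v; m}})))
  }
  ut <- model$params$utilities
  se_of <- function(value, pct) {
    hr <- pct / 100 * value
    if (util_var_mode == "ci_half_range") hr / 1.96 else hr
  }
  for (k in names(ut$state)) {
    pct <- ut$state_var[[k]]
    if (is.na(pct)) next
    add(list(id = paste0("utility:", k), family = "beta",
             central = ut$state[[k]], se = se_of(ut$state[[k]], pct),
             support = c(0, 1),
             patch = local({kk <- k; function(m, v) {m$params$utilities$state[[kk]] <- v; m}})))
  }
  for (k in names(ut$strategy)) {
    pct <- ut$strategy_var[[k]]
    if (is.na(pct)) next
    add(list(id = paste0("utility:", k), family = "beta",
             central = ut$strategy[[k]], se = se_of(ut$strategy[[k]], pct),
             support = c(0, 1),
             patch = local({kk <- k; function(m, v) {m$params$utilities$strategy[[kk]] <- v; m}})))
  }
  money <- c("one_off", "recurring", "annuity", "bc", "oc", "palliative")
  for (sec in money) for (k in names(model$costs[[sec]])) {
    v <- model$costs[[sec]][[k]]
    if (!is.numeric(v) || v <= 0) next
    add(list(id = paste0("cost:", sec, ":", k), family = "gamma",
             central = v, se = cost_se_frac * v, support = c(0, Inf),
             patch = local({ss <- sec; kk <- k
                            function(m, val) {m$costs[[ss]][[kk]] <- val; m}})))
  }
  for (k in c("total_tnbc", "total_hrpos", "total_her2")) {
    v <- model$costs$mbc[[k]]
    add(list(id = paste0("cost:mbc:", k), family = "gamma",
             central = v, se = cost_se_frac * v, support = c(0, Inf),
             patch = local({kk <- k; function(m, val) {m$costs$mbc[[kk]] <- val; m}})))
  }
  structure(out, class = "uncertain_set")
}

#' Fit a sampling distribution to an uncertain parameter
#'
#' Method-of-moments parameterisation matching mean = central and
#' sd = SE: gamma (shape = m^2/s^2, scale = s^2/m) for rates and costs,
#' lognormal with moments matched on the natural scale for hazard ratios,
#' beta with matched moments for utilities, uniform over a published range.
#' An SE of zero yields a degenerate point mass.
#'
#' @param param One element of [uncertain_parameters()].
#' @return A function of `n` returning `n` random draws.
#' @export
fit_distribution <- function(param) {
  m <- param$central; s <- param$se
  switch(param$family,
    uniform = {
      lo <- param$lo; hi <- param$hi
      function(n) stats::runif(n, lo, hi)
    },
    gamma = {
      if (s == 0 || m == 0) return(function(n) rep(m, n))
      shape <- m^2 / s^2; scale <- s^2 / m
      function(n) stats::rgamma(n, shape = shape, scale = scale)
    },
    lognormal = {
      if (s == 0) return(function(n) rep(m, n))
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      function(n) stats::rlnorm(n, meanlog, sdlog)
    },
    beta = {
      if (s == 0) return(function(n) rep(m, n))
      v <- s^2
      if (v >= m * (1 - m))
        stop("SE ", s, " incompatible with beta support for mean ", m)
      a <- m * (m * (1 - m) / v - 1)
      b <- (1 - m) * (m * (1 - m) / v - 1)
      function(n) stats::rbeta(n, a, b)
    },
    stop("unknown distribution family: ", param$family))
}

# Re-assemble a model bundle after patching params/costs.
.rebuild_model <- function(model) {
  build_model(model$mutation, params = model$params,
              life_table = model$life_table, costs = model$costs,
              config = model$config, strategies = model$strategies)
}

.run_totals <- function(model, strategies) {
  t(vapply(strategies, function(s) {
    out <- accumulate_outcomes(run_cohort(s, model), model)
    c(cost = out$cost, qaly = out$qaly, ly = out$ly)
  }, numeric(3)))
}

#' Probabilistic sensitivity analysis
#'
#' Draws all uncertain parameters jointly and independently from their
#' assigned distributions, re-runs the full model per draw, and applies the
#' same draw to every strategy within an iteration (common random numbers).
#' Iterations producing non-finite output are flagged and excluded from the
#' summaries; the run continues.
#'
#' @param fit A `cua_fit` (base-case analysis to perturb).
#' @param n Number of iterations (10,000 in the full analysis).
#' @param seed Integer seed; identical seed and configuration reproduce the
#'   output bit for bit.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve;
#'   defaults to 21 points from 0 to twice the configured threshold.
#' @param cost_se_frac,util_var_mode Passed to [uncertain_parameters()].
#' @return Object of class `cua_psa`: per-iteration cost/QALY/LY arrays per
#'   strategy, the CEAC, and the probability each strategy is optimal at the
#'   configured willingness-to-pay.
#' @export
run_psa <- function(fit, n = 10000, seed = NULL, wtp_grid = NULL,
                    cost_se_frac = 0.2, util_var_mode = "ci_half_range") {
  if (n < 1) stop("n must be a positive iteration count")
  if (!is.null(seed)) set.seed(seed)
  model <- fit$model
  strategies <- fit$totals$strategy
  ups <- uncertain_parameters(model, cost_se_frac, util_var_mode)
  draws <- vapply(ups, function(p) fit_distribution(p)(n), numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- vapply(ups, `[[`, character(1), "id")
  S <- length(strategies)
  cost <- qaly <- ly <- matrix(NA_real_, n, S, dimnames = list(NULL, strategies))
  flagged <- integer(0)
  for (i in seq_len(n)) {
    m <- model
    for (j in seq_along(ups)) m <- ups[[j]]$patch(m, draws[i, j])
    m <- .rebuild_model(m)
    tot <- tryCatch(.run_totals(m, strategies), error = function(e) NULL)
    if (is.null(tot) || any(!is.finite(tot))) {
      flagged <- c(flagged, i)
      next
    }
    cost[i, ] <- tot[, "cost"]; qaly[i, ] <- tot[, "qaly"]; ly[i, ] <- tot[, "ly"]
  }
  wtp0 <- wtp_value(model$config)
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 2 * wtp0, length.out = 21)
  ok <- setdiff(seq_len(n), flagged)
  ceac <- vapply(wtp_grid, function(w) {
    nb <- w * qaly[ok, , drop = FALSE] - cost[ok, , drop = FALSE]
    best <- max.col(nb, ties.method = "first")
    tabulate(best, S) / length(ok)
  }, numeric(S))
  ceac <- t(ceac)
  colnames(ceac) <- strategies
  nb0 <- wtp0 * qaly[ok, , drop = FALSE] - cost[ok, , drop = FALSE]
  p_opt <- tabulate(max.col(nb0, ties.method = "first"), S) / length(ok)
  names(p_opt) <- strategies
  structure(list(mutation = fit$mutation, n = n, seed = seed,
                 strategies = strategies, cost = cost, qaly = qaly, ly = ly,
                 draws = draws, flagged = flagged,
                 wtp_grid = wtp_grid, ceac = ceac, wtp = wtp0,
                 prob_optimal = p_opt),
            class = "cua_psa")
}

#' @export
print.cua_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$mutation, "|", x$n,
      "iterations")
  if (length(x$flagged)) cat(" (", length(x$flagged), " flagged non-finite)")
  cat("\nProbability cost-effective at WTP", sprintf("%.0f", x$wtp), ":\n")
  for (s in names(sort(x$prob_optimal, decreasing = TRUE)))
    cat(sprintf("  %-9s %6.3f\n", s, x$prob_optimal[[s]]))
  invisible(x)
}

#' Mean PSA results per strategy
#' @param object A `cua_psa`.
#' @param ... Unused.
#' @return Data frame of PSA-mean cost/QALY/LY per strategy.
#' @export
summary.cua_psa <- function(object, ...) {
  ok <- setdiff(seq_len(object$n), object$flagged)
  data.frame(strategy = object$strategies,
             cost = colMeans(object$cost[ok, , drop = FALSE]),
             qaly = colMeans(object$qaly[ok, , drop = FALSE]),
             ly = colMeans(object$ly[ok, , drop = FALSE]),
             prob_optimal = as.numeric(object$prob_optimal),
             row.names = NULL)
}

#' Incremental cost-effectiveness scatter of a PSA
#'
#' Plots each iteration's incremental cost against incremental QALYs versus
#' the reference strategy, one colour per strategy.
#'
#' @param x A `cua_psa`.
#' @param reference Reference strategy.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cua_psa <- function(x, reference = "IS", ...) {
  ri <- match(reference, x$strategies)
  others <- setdiff(seq_along(x$strategies), ri)
  dq <- x$qaly[, others, drop = FALSE] - x$qaly[, ri]
  dc <- x$cost[, others, drop = FALSE] - x$cost[, ri]
  cols <- seq_along(others) + 1
  graphics::plot(range(dq, na.rm = TRUE), range(dc, na.rm = TRUE), type = "n",
                 xlab = "Incremental QALYs", ylab = "Incremental cost",
                 main = paste("PSA scatter,", x$mutation), ...)
  for (j in seq_along(others))
    graphics::points(dq[, j], dc[, j], col = cols[j], pch = 20, cex = 0.4)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::legend("topleft", legend = x$strategies[others], col = cols,
                   pch = 20, cex = 0.8)
  invisible(x)
}

#' Export PSA scatter and CEAC as CSV
#' @param psa A `cua_psa`.
#' @param scatter_path,ceac_path Output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
export_psa <- function(psa, scatter_path = NULL, ceac_path = NULL) {
  if (!is.null(scatter_path)) {
    df <- data.frame(iteration = rep(seq_len(psa$n), length(psa$strategies)),
                     strategy = rep(psa$strategies, each = psa$n),
                     cost = as.vector(psa$cost), qaly = as.vector(psa$qaly))
    utils::write.csv(format(df, nsmall = 6), scatter_path, row.names = FALSE)
  }
  if (!is.null(ceac_path)) {
    df <- data.frame(wtp = psa$wtp_grid, psa$ceac)
    utils::write.csv(format(df, nsmall = 6), ceac_path, row.names = FALSE)
  }
  invisible(c(scatter_path, ceac_path))
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies each uncertain parameter to its low and high bound (central
#' -/+ 1.96 SE, truncated to the parameter's support, or the published
#' range ends), holding all others at their central values, and records the
#' incremental net monetary benefit of `strategy` versus `comparator` at the
#' configured willingness-to-pay (and the ICER when defined). Bars are
#' sorted by width, widest first.
#'
#' @param fit A `cua_fit`.
#' @param strategy Strategy whose comparison is profiled.
#' @param comparator Comparator (default the reference strategy).
#' @param params Optional [uncertain_parameters()] subset.
#' @return Data frame of class `cua_tornado`.
#' @export
tornado <- function(fit, strategy = "PBM_PBSO", comparator = "IS",
                    params = NULL) {
  model <- fit$model
  if (is.null(params)) params <- uncertain_parameters(model)
  wtp <- wtp_value(model$config)
  eval_nmb <- function(m) {
    tot <- .run_totals(m, c(comparator, strategy))
    inc <- incremental(as.list(as.data.frame(t(tot[1, ]))),
                       as.list(as.data.frame(t(tot[2, ]))))
    c(nmb = wtp * inc$d_qaly - inc$d_cost,
      icer = if (is.na(inc$icer)) NA_real_ else inc$icer)
  }
  base_nmb <- eval_nmb(model)[["nmb"]]
  rows <- lapply(params, function(p) {
    if (p$family == "uniform") {
      lo <- p$lo; hi <- p$hi
    } else {
      lo <- max(p$support[1], p$central - 1.96 * p$se)
      hi <- min(p$support[2], p$central + 1.96 * p$se)
    }
    r_lo <- eval_nmb(.rebuild_model(p$patch(model, lo)))
    r_hi <- eval_nmb(.rebuild_model(p$patch(model, hi)))
    data.frame(parameter = p$id, low = lo, high = hi,
               nmb_low = r_lo[["nmb"]], nmb_high = r_hi[["nmb"]],
               icer_low = r_lo[["icer"]], icer_high = r_hi[["icer"]],
               width = abs(r_hi[["nmb"]] - r_lo[["nmb"]]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_nmb") <- base_nmb
  attr(out, "comparison") <- paste(strategy, "vs", comparator)
  class(out) <- c("cua_tornado", "data.frame")
  out
}

#' @export
print.cua_tornado <- function(x, n = 10, ...) {
  cat("Tornado analysis (incremental NMB),", attr(x, "comparison"),
      "| base NMB", sprintf("%.0f", attr(x, "base_nmb")), "\n")
  print(utils::head(as.data.frame(x)[, c("parameter", "nmb_low", "nmb_high",
                                         "width")], n), row.names = FALSE)
  invisible(x)
}

#' Horizontal-bar tornado plot
#' @param x A `cua_tornado`.
#' @param n Number of widest bars to show.
#' @param ... Unused.
#' @export
plot.cua_tornado <- function(x, n = 12, ...) {
  d <- utils::head(as.data.frame(x), n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_nmb")
  graphics::par(mar = c(4, 14, 2, 1))
  graphics::plot(range(c(d$nmb_low, d$nmb_high)), c(0.5, nrow(d) + 0.5),
                 type = "n", yaxt = "n", xlab = "Incremental NMB",
                 ylab = "", main = attr(x, "comparison"))
  for (i in seq_len(nrow(d)))
    graphics::segments(d$nmb_low[i], i, d$nmb_high[i], i, lwd = 8,
                       col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}
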
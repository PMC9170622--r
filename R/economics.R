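# Comparative cost-effectiveness: incremental analysis, dominance, NMB.

#' Incremental comparison of two strategy results
#'
#' Differences are `b - a`. An ICER is reported only when the comparator is
#' both more costly and more effective; otherwise the comparison is labelled
#' `"dominant"` (cheaper and more effective) or `"dominated"` (costlier and
#' less effective). Equal-effect comparisons are labelled, never divided.
#'
#' @param a,b Lists/rows with elements `cost`, `qaly`, `ly`.
#' @return List with `d_cost`, `d_qaly`, `d_ly`, `icer` (number or `NA`)
#'   and `label`.
#' @export
incremental <- function(a, b) {
  d_cost <- b$cost - a$cost
  d_qaly <- b$qaly - a$qaly
  d_ly <- (b$ly %||% NA_real_) - (a$ly %||% NA_real_)
  if (d_cost == 0 && d_qaly == 0) {
    label <- "reference"; icer <- NA_real_
  } else if (d_cost > 0 && d_qaly > 0) {
    icer <- d_cost / d_qaly; label <- sprintf("%.0f", icer)
  } else if (d_cost <= 0 && d_qaly >= 0) {
    label <- "dominant"; icer <- NA_real_
  } else if (d_cost >= 0 && d_qaly <= 0) {
    label <- "dominated"; icer <- NA_real_
  } else {
    # cheaper and less effective: a ratio would be ambiguous
    label <- "less costly, less effective"; icer <- NA_real_
  }
  list(d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly, icer = icer, label = label)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Net monetary benefit
#'
#' @param result List/row with `cost` and `qaly`.
#' @param wtp Willingness-to-pay per QALY (same currency as `cost`).
#' @return `wtp * qaly - cost`.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative")
  wtp * result$qaly - result$cost
}

#' Dominance classification of a strategy set
#'
#' Sorts strategies by cost, marks absolute dominance (some other strategy
#' costs no more and yields at least as many QALYs, one comparison strict)
#' and extended dominance (a strategy off the cost/QALY efficiency frontier:
#' its frontier ICER exceeds that of the next more effective option), and
#' computes ICERs along the frontier.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly`.
#' @return The data frame sorted by cost with added `dominance` and
#'   `frontier_icer` columns.
#' @export
dominance_frontier <- function(results) {
  if (nrow(results) < 2) stop("need at least two strategies")
  res <- results[order(results$cost, results$qaly), , drop = FALSE]
  n <- nrow(res)
  dom <- rep("nondominated", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    abs_dom <- any(res$cost[others] <= res$cost[i] &
                     res$qaly[others] >= res$qaly[i] &
                     (res$cost[others] < res$cost[i] |
                        res$qaly[others] > res$qaly[i]))
    if (abs_dom) dom[i] <- "absolutely_dominated"
  }
  # extended dominance on the remaining candidates, by iterated ICER check
  repeat {
    cand <- which(dom == "nondominated")
    if (length(cand) < 3) break
    cc <- cand[order(res$cost[cand])]
    icers <- diff(res$cost[cc]) / diff(res$qaly[cc])
    bad <- which(diff(icers) < 0)  # ICER not increasing along frontier
    if (!length(bad)) break
    dom[cc[bad[1] + 1]] <- "extendedly_dominated"
  }
  front <- which(dom == "nondominated")
  front <- front[order(res$cost[front])]
  res$frontier_icer <- NA_real_
  if (length(front) > 1)
    res$frontier_icer[front[-1]] <-
      diff(res$cost[front]) / diff(res$qaly[front])
  # a strategy cheaper and more effective than every comparator is dominant
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (all(res$cost[i] < res$cost[others]) && all(res$qaly[i] > res$qaly[others]))
      dom[i] <- "dominant"
  }
  res$dominance <- dom
  res
}

#' Build the comparative league table
#'
#' Mirrors the base-case results layout: per-strategy discounted totals, the
#' differences against the reference strategy (intensified surveillance),
#' the ICER-or-label column, and the dominance classification.
#'
#' @param totals Data frame with `strategy`, `cost`, `qaly`, `ly`.
#' @param reference Reference strategy name (default `"IS"`).
#' @return Data frame of class `league_table`.
#' @export
league_table <- function(totals, reference = "IS") {
  if (!reference %in% totals$strategy)
    stop("reference strategy '", reference, "' not among results")
  ref <- totals[totals$strategy == reference, ]
  rows <- lapply(seq_len(nrow(totals)), function(i) {
    inc <- incremental(ref, totals[i, ])
    data.frame(strategy = totals$strategy[i], cost = totals$cost[i],
               qaly = totals$qaly[i], ly = totals$ly[i],
               d_cost = inc$d_cost, d_qaly = inc$d_qaly, d_ly = inc$d_ly,
               icer = if (totals$strategy[i] == reference) "reference" else inc$label)
  })
  lt <- do.call(rbind, rows)
  dm <- dominance_frontier(totals[, c("strategy", "cost", "qaly")])
  lt$dominance <- dm$dominance[match(lt$strategy, dm$strategy)]
  lt <- lt[order(lt$cost, decreasing = TRUE), ]
  rownames(lt) <- NULL
  class(lt) <- c("league_table", "data.frame")
  lt
}

#' @export
print.league_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$cost <- sprintf("%.0f", df$cost)
  df$qaly <- sprintf("%.2f", df$qaly)
  df$ly <- sprintf("%.2f", df$ly)
  df$d_cost <- sprintf("%.0f", df$d_cost)
  df$d_qaly <- sprintf("%.2f", df$d_qaly)
  df$d_ly <- sprintf("%.2f", df$d_ly)
  print(df, row.names = FALSE)
  invisible(x)
}
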
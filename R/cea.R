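# Cost-effectiveness analysis: dominance classification, frontier ICERs,
# and net monetary benefit at the willingness-to-pay thresholds.

#' Net monetary benefit
#'
#' `NMB = QALYs x willingness-to-pay - cost`. The strategy with the highest
#' NMB at a threshold is the cost-effective choice at that threshold.
#'
#' @param cost Cost per person (US$).
#' @param qaly Effect per person (QALYs).
#' @param wtp Willingness-to-pay threshold (US$/QALY, >= 0).
#' @return NMB in US$.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  qaly * wtp - cost
}

#' Combine sex-specific strategy results into a national-cohort estimate
#'
#' Convex combination of costs, QALYs and event counts with weight
#' `male_fraction` on the male result, mirroring the census-proportion
#' aggregation of the sex-specific model runs.
#'
#' @param male,female One-row data.frames from [evaluate_strategy()] sharing
#'   `strategy`, `perspective` and `start_age`.
#' @param male_fraction Fraction of the cohort that is male, in `[0, 1]`.
#' @return A one-row data.frame with `sex = "ALL"`.
#' @export
aggregate_sexes <- function(male, female, male_fraction) {
  if (male_fraction < 0 || male_fraction > 1) {
    stop("`male_fraction` must lie in [0, 1]", call. = FALSE)
  }
  keys <- c("strategy", "perspective", "start_age")
  for (k in keys) {
    if (!identical(male[[k]], female[[k]])) {
      stop("mismatched `", k, "` between sex-specific results", call. = FALSE)
    }
  }
  out <- male
  out$sex <- "ALL"
  for (k in c("cost", "qaly", "lifetime_events", "lifetime_cvd_deaths")) {
    out[[k]] <- male_fraction * male[[k]] + (1 - male_fraction) * female[[k]]
  }
  out
}

#' Efficiency frontier with dominance classification
#'
#' Sorts strategies by ascending cost (ties by descending QALYs, then
#' strategy id), marks strong dominance (costing at least as much as another
#' strategy that yields at least as many QALYs; equal-QALY higher-cost folded
#' in), then iteratively removes extended-dominated strategies (whose
#' incremental cost-effectiveness ratio against the previous frontier
#' strategy exceeds the next one's) until frontier ICERs strictly increase.
#'
#' @param results Data.frame with columns `strategy`, `cost`, `qaly`
#'   (unique strategy ids).
#' @return Data.frame sorted by cost with added `status` (`"frontier"`,
#'   `"strongly_dominated"`, `"extended_dominated"`), `icer` (vs the
#'   previous cheaper frontier strategy; `NA` for the cheapest and for
#'   dominated rows) and `dominated_icer` (the pre-removal ICER of
#'   extended-dominated rows).
#' @export
efficiency_frontier <- function(results) {
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(results)))
  if (nrow(results) < 1) stop("need at least one strategy", call. = FALSE)
  if (anyDuplicated(results$strategy)) {
    stop("duplicate strategy ids", call. = FALSE)
  }
  df <- results[order(results$cost, -results$qaly, results$strategy), ,
                drop = FALSE]
  n <- nrow(df)
  status <- rep("frontier", n)
  # strong dominance: some other strategy is no worse on both axes and not
  # an exact duplicate ranked later
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better <- df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i]
      strict <- df$cost[j] < df$cost[i] || df$qaly[j] > df$qaly[i]
      tie_first <- df$cost[j] == df$cost[i] && df$qaly[j] == df$qaly[i] &&
        j < i
      if (better && (strict || tie_first)) {
        status[i] <- "strongly_dominated"
        break
      }
    }
  }
  dominated_icer <- rep(NA_real_, n)
  repeat {
    idx <- which(status == "frontier")
    if (length(idx) < 3) break
    icers <- diff(df$cost[idx]) / diff(df$qaly[idx])
    drop <- which(diff(icers) < 0)  # icer[k] > icer[k+1]: strategy idx[k+1]
    if (length(drop) == 0) break
    victim <- idx[drop[1] + 1]
    dominated_icer[victim] <- icers[drop[1]]
    status[victim] <- "extended_dominated"
  }
  idx <- which(status == "frontier")
  icer <- rep(NA_real_, n)
  if (length(idx) > 1) {
    icer[idx[-1]] <- diff(df$cost[idx]) / diff(df$qaly[idx])
  }
  df$status <- status
  df$icer <- icer
  df$dominated_icer <- dominated_icer
  rownames(df) <- NULL
  df
}

#' League table: frontier plus net monetary benefit at each threshold
#'
#' @param results Data.frame with `strategy`, `cost`, `qaly`.
#' @param wtp Named numeric vector of willingness-to-pay thresholds
#'   (default: the packaged 1x and 3x GDP-per-capita thresholds).
#' @return The [efficiency_frontier()] table with one `nmb_<name>` column
#'   per threshold.
#' @export
league_table <- function(results, wtp = default_parameters()$wtp_thresholds) {
  ft <- efficiency_frontier(results)
  for (k in seq_along(wtp)) {
    nm <- names(wtp)[k]
    if (is.null(nm) || nm == "") nm <- paste0("wtp", k)
    ft[[paste0("nmb_", nm)]] <-
      net_monetary_benefit(ft$cost, ft$qaly, wtp[[k]])
  }
  ft
}

#' Pairwise ICERs against a fixed comparator
#'
#' Secondary output used for within-strategy comparisons (e.g. starting-age
#' subgroups compared against the cheapest age): incremental cost divided by
#' incremental QALYs of each strategy against one reference row.
#'
#' @param results Data.frame with `strategy`, `cost`, `qaly`.
#' @param comparator Strategy id of the reference.
#' @return `results` with added `icer_vs_comparator` (`NA` for the
#'   comparator itself).
#' @export
pairwise_icers <- function(results, comparator) {
  i <- match(comparator, results$strategy)
  if (is.na(i)) stop("comparator not found: ", comparator, call. = FALSE)
  dc <- results$cost - results$cost[i]
  dq <- results$qaly - results$qaly[i]
  results$icer_vs_comparator <- ifelse(seq_len(nrow(results)) == i,
                                       NA_real_, dc / dq)
  results
}
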
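# Probabilistic sensitivity analysis: moment-matched sampling of the
# parameter set (gamma costs, beta utilities and transition probabilities,
# lognormal treatment effects), Monte Carlo propagation with common random
# numbers across strategies, and cost-effectiveness acceptability curves.

# One draw from a moment-matched distribution; se = 0 is degenerate.
.draw_one <- function(family, mean, se) {
  if (se == 0 || mean == 0) return(mean)
  p <- moment_match(family, mean, se)
  switch(family,
    gamma = stats::rgamma(1, shape = p$shape, scale = p$scale),
    beta = stats::rbeta(1, p$alpha, p$beta),
    lognormal = stats::rlnorm(1, p$meanlog, p$sdlog))
}

.draw_vec <- function(family, means, se_rel) {
  vapply(means, function(m) .draw_one(family, m, se_rel * m), numeric(1))
}

#' Draw one random parameter set for the PSA
#'
#' Each stochastic parameter is replaced by a draw from its moment-matched
#' distribution: gamma for costs (relative SE from `psa_spec$se_rel_cost`),
#' beta for utilities and all transition/mortality/case-fatality
#' probabilities, lognormal for treatment-effect relative risks. Structural
#' values (discount rate, thresholds, stroke weight, male fraction, config)
#' are untouched; death-state utilities stay 0. If a draw breaches a joint
#' parameter-set invariant the whole set is redrawn (never truncated), up to
#' 100 attempts.
#'
#' Uses the current R RNG stream; seed management (one independent substream
#' per draw) is done by [run_psa()].
#'
#' @param ps Base `cvd_params` object.
#' @return A validated `cvd_params` object.
#' @export
draw_parameter_set <- function(ps) {
  spec <- ps$psa_spec
  for (attempt in seq_len(100)) {
    draw <- unclass(ps)
    for (sex in c("M", "F")) {
      ri <- ps$risk_incidence[[sex]]
      draw$risk_incidence[[sex]][] <- .draw_vec("beta", as.vector(ri),
                                                spec$se_rel_tp)
      draw$background_mortality[[sex]][] <-
        .draw_vec("beta", ps$background_mortality[[sex]], spec$se_rel_tp)
      draw$cfr_stroke[[sex]][] <- .draw_vec("beta", ps$cfr_stroke[[sex]],
                                            spec$se_rel_tp)
      draw$cfr_ihd[[sex]][] <- .draw_vec("beta", ps$cfr_ihd[[sex]],
                                         spec$se_rel_tp)
    }
    draw$acvd_tp[] <- .draw_vec("beta", ps$acvd_tp, spec$se_rel_tp)
    draw$recurrent_acvd_tp[] <- .draw_vec("beta", ps$recurrent_acvd_tp,
                                          spec$se_rel_tp)
    draw$costs[] <- .draw_vec("gamma", ps$costs, spec$se_rel_cost)
    live <- setdiff(names(ps$utilities), c("CVD_DEATH", "NONCVD_DEATH"))
    draw$utilities[live] <- .draw_vec("beta", ps$utilities[live],
                                      spec$se_rel_utility)
    draw$effects[] <- .draw_vec("lognormal", ps$effects, spec$se_rel_effect)
    # lognormal effect draws may exceed 1; clip check via validation
    out <- structure(draw, class = "cvd_params")
    if (isTRUE(validate_parameters(out, quiet = TRUE))) return(out)
  }
  stop("could not draw a valid parameter set in 100 attempts", call. = FALSE)
}

#' Run the probabilistic sensitivity analysis
#'
#' For each Monte Carlo draw, one random parameter set is sampled and every
#' scenario and sex is evaluated with that same set (common random numbers
#' across strategies). Draw `i` uses its own RNG substream whose seed is
#' derived from the base seed and the draw index, so any draw is
#' reproducible independently of the others, the full run is deterministic
#' given `seed`, and different base seeds give essentially disjoint
#' substreams.
#'
#' @param ps Base `cvd_params` object.
#' @param scenarios Scenarios to evaluate (default all four).
#' @param n_draws Number of Monte Carlo draws (the published analysis used
#'   10,000).
#' @param seed Integer base seed.
#' @param sexes Subset of `c("M", "F")`.
#' @param perspective `"provider"` or `"societal"`.
#' @param start_age,end_age As in [run_cohort()].
#' @return Object of class `cvd_psa`: arrays `cost` and `qaly` of dimension
#'   draws x scenarios x sexes, plus the run settings.
#' @export
run_psa <- function(ps, scenarios = cvd_scenarios(), n_draws = 10000,
                    seed = 1, sexes = c("M", "F"),
                    perspective = c("provider", "societal"),
                    start_age = 45, end_age = 100) {
  perspective <- match.arg(perspective)
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  dims <- list(draw = NULL, strategy = scenarios, sex = sexes)
  cost <- array(NA_real_, c(n_draws, length(scenarios), length(sexes)),
                dimnames = dims)
  qaly <- cost
  for (i in seq_len(n_draws)) {
    # per-draw substream: mix the base seed and draw index so streams are
    # independently reproducible and distinct across base seeds
    set.seed(as.integer((as.numeric(seed) * 69069 + i * 12345) %%
                          2147483647))
    psi <- tryCatch(draw_parameter_set(ps), error = function(e) {
      stop("PSA draw ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    for (sx in seq_along(sexes)) {
      for (sc in seq_along(scenarios)) {
        r <- evaluate_strategy(psi, scenarios[sc], sexes[sx], perspective,
                               start_age, end_age)
        cost[i, sc, sx] <- r$cost
        qaly[i, sc, sx] <- r$qaly
      }
    }
  }
  structure(list(cost = cost, qaly = qaly, n_draws = n_draws, seed = seed,
                 scenarios = scenarios, sexes = sexes,
                 perspective = perspective, start_age = start_age),
            class = "cvd_psa")
}

#' @export
print.cvd_psa <- function(x, ...) {
  cat("<cvd_psa> ", x$n_draws, " draws, seed ", x$seed, ", ",
      paste(x$scenarios, collapse = "/"), ", sexes ",
      paste(x$sexes, collapse = "/"), ", ", x$perspective,
      " perspective\n", sep = "")
  invisible(x)
}

#' Default willingness-to-pay grid for acceptability curves
#'
#' 0 to 3x GDP per capita in US$200 steps, always including the exact 1x
#' and 3x GDP-per-capita thresholds.
#' @param ps A `cvd_params` object supplying the thresholds.
#' @return Sorted numeric vector.
#' @export
default_wtp_grid <- function(ps = default_parameters()) {
  sort(unique(c(seq(0, 4200, by = 200), unname(ps$wtp_thresholds))))
}

#' Cost-effectiveness acceptability curves
#'
#' For each strategy, sex and threshold, the fraction of PSA draws in which
#' the strategy's net monetary benefit strictly exceeds the comparator's
#' (pairwise CEAC against the base scenario by default). With
#' `rule = "max_nmb"` the curve is instead the fraction of draws in which
#' the strategy attains the maximum NMB among all evaluated strategies.
#'
#' @param res A `cvd_psa` object.
#' @param comparator Strategy id compared against (default `"BASE"`).
#' @param wtp_grid Thresholds at which to evaluate the curves.
#' @param rule `"pairwise"` (default) or `"max_nmb"`.
#' @return Data.frame with columns `wtp`, `strategy`, `sex`, `probability`.
#' @export
ceac <- function(res, comparator = "BASE",
                 wtp_grid = default_wtp_grid(), rule = c("pairwise",
                                                         "max_nmb")) {
  rule <- match.arg(rule)
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid",
                                  call. = FALSE)
  ci <- match(comparator, res$scenarios)
  if (rule == "pairwise" && is.na(ci)) {
    stop("comparator not in PSA scenarios: ", comparator, call. = FALSE)
  }
  out <- list()
  for (sx in seq_along(res$sexes)) {
    for (sc in seq_along(res$scenarios)) {
      prob <- vapply(wtp_grid, function(l) {
        nmb <- l * res$qaly[, , sx, drop = FALSE] -
          res$cost[, , sx, drop = FALSE]
        if (rule == "pairwise") {
          mean(nmb[, sc, 1] > nmb[, ci, 1])
        } else {
          mean(nmb[, sc, 1] >= apply(nmb[, , 1, drop = FALSE], 1, max))
        }
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        wtp = wtp_grid, strategy = res$scenarios[sc], sex = res$sexes[sx],
        probability = prob, stringsAsFactors = FALSE)
    }
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' Cost-effectiveness plane coordinates
#'
#' Incremental cost and incremental QALYs of each strategy against the
#' comparator, per draw, for scatter-plane plots or CSV export.
#'
#' @param res A `cvd_psa` object.
#' @param comparator Strategy id (default `"BASE"`).
#' @return Data.frame with `draw`, `strategy`, `sex`, `inc_cost`,
#'   `inc_qaly`.
#' @export
ce_plane <- function(res, comparator = "BASE") {
  ci <- match(comparator, res$scenarios)
  if (is.na(ci)) stop("comparator not in PSA scenarios: ", comparator,
                      call. = FALSE)
  out <- list()
  for (sx in seq_along(res$sexes)) {
    for (sc in seq_along(res$scenarios)) {
      if (sc == ci) next
      out[[length(out) + 1]] <- data.frame(
        draw = seq_len(res$n_draws),
        strategy = res$scenarios[sc],
        sex = res$sexes[sx],
        inc_cost = res$cost[, sc, sx] - res$cost[, ci, sx],
        inc_qaly = res$qaly[, sc, sx] - res$qaly[, ci, sx],
        stringsAsFactors = FALSE)
    }
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}
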
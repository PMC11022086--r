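# Nine-state Markov cohort engine: per-cycle transition matrices, cohort
# trace propagation, and discounted cost/QALY accumulation.
#
# States: GEN (general population, <10% 10-year risk, unknown), four
# screened 10-year risk bands (R10 = 10-19.9%, R20 = 20-29.9%,
# R30 = 30-39.9%, R40 = >=40%), ACVD (acute event, one-cycle tunnel),
# CHRONIC (established CVD), and the two absorbing death states.

#' Model state names, in matrix order
#' @return Character vector of the nine state names.
#' @export
cvd_states <- function() {
  c("GEN", "R10", "R20", "R30", "R40", "ACVD", "CHRONIC",
    "CVD_DEATH", "NONCVD_DEATH")
}

#' Intervention scenario names
#'
#' `BASE` (no screening or prevention), `SC_PP_SP` (screening + primary +
#' secondary prevention), `SC_PP` (screening + primary prevention) and `SP`
#' (secondary prevention only).
#' @return Character vector of the four scenario names.
#' @export
cvd_scenarios <- function() c("BASE", "SC_PP_SP", "SC_PP", "SP")

# Per-scenario attachments: which states carry an annual intervention cost
# and which transitions carry a treatment-effect multiplier.
.scenario_spec <- function(ps, scenario) {
  scenario <- match.arg(scenario, cvd_scenarios())
  has_scpp <- scenario %in% c("SC_PP_SP", "SC_PP")
  has_sp <- scenario %in% c("SC_PP_SP", "SP")
  eff <- function(x) if (isTRUE(ps$config$effect_is_multiplier)) x else 1 - x
  pp_mult <- c(R10 = 1, R20 = 1, R30 = 1, R40 = 1)
  if (has_scpp) {
    pp_mult["R20"] <- eff(ps$effects[["pp_mid"]])
    pp_mult[c("R30", "R40")] <- eff(ps$effects[["pp_high"]])
  }
  sp_mult <- if (has_sp) eff(ps$effects[["sp"]]) else 1
  state_cost <- stats::setNames(numeric(9), cvd_states())
  if (has_scpp) {
    state_cost[c("GEN", "R10")] <- ps$costs[["screening"]]
    state_cost["R20"] <- ps$costs[["pp_mid"]]
    state_cost[c("R30", "R40")] <- ps$costs[["pp_high"]]
  }
  if (has_sp) state_cost["CHRONIC"] <- ps$costs[["sp"]]
  list(scenario = scenario, pp_mult = pp_mult, sp_mult = sp_mult,
       state_cost = state_cost)
}

#' Build the one-cycle transition matrix for a scenario, sex and age
#'
#' Row-stochastic 9x9 matrix. The general population moves into the four
#' risk bands at the published annual incidences and to non-CVD death at the
#' background mortality; risk bands move to ACVD at the band's annual
#' acute-event probability (scaled by the primary-prevention relative risk
#' where the scenario treats that band) or to non-CVD death; ACVD is a
#' one-cycle tunnel resolved by the composite case fatality first, then
#' background mortality among acute survivors, the rest moving to CHRONIC;
#' CHRONIC moves back to ACVD at the recurrent-event probability (scaled by
#' the secondary-prevention relative risk where applicable); the two death
#' states are absorbing. Transitions not listed are structural zeros.
#'
#' @param ps A `cvd_params` object.
#' @param scenario One of [cvd_scenarios()].
#' @param sex `"M"` or `"F"`.
#' @param age Age in years at the start of the cycle.
#' @return A 9x9 matrix with `dimnames` [cvd_states()].
#' @export
build_transition_matrix <- function(ps, scenario, sex, age) {
  sc <- .scenario_spec(ps, scenario)
  sex <- match.arg(sex, c("M", "F"))
  ri <- ps$risk_incidence[[sex]]
  .transition_core(
    ps, sc,
    inc = ri[.risk_band_row(rownames(ri), age), ],
    m = band_lookup(ps$background_mortality[[sex]], age),
    cfr = composite_case_fatality(ps, sex, age),
    rec = band_lookup(ps$recurrent_acvd_tp, age),
    age = age)
}

# Build one matrix from pre-resolved banded inputs (risk incidences `inc`,
# background mortality `m`, composite case fatality `cfr`, recurrent
# probability `rec`).
.transition_core <- function(ps, sc, inc, m, cfr, rec, age = NA) {
  s <- cvd_states()
  M <- matrix(0, 9, 9, dimnames = list(s, s))

  stay <- 1 - sum(inc) - m
  if (stay < 0) stop("parameter infeasibility: general-population outflow ",
                     "exceeds 1 at age ", age, call. = FALSE)
  M["GEN", c("R10", "R20", "R30", "R40")] <- inc
  M["GEN", "NONCVD_DEATH"] <- m
  M["GEN", "GEN"] <- stay

  for (k in c("R10", "R20", "R30", "R40")) {
    p_acvd <- ps$acvd_tp[[k]] * sc$pp_mult[[k]]
    stay <- 1 - p_acvd - m
    if (stay < 0) stop("parameter infeasibility in risk band ", k,
                       " at age ", age, call. = FALSE)
    M[k, "ACVD"] <- p_acvd
    M[k, "NONCVD_DEATH"] <- m
    M[k, k] <- stay
  }

  m_acvd <- if (isTRUE(ps$config$acvd_background_mortality)) m else 0
  M["ACVD", "CVD_DEATH"] <- cfr
  M["ACVD", "NONCVD_DEATH"] <- (1 - cfr) * m_acvd
  M["ACVD", "CHRONIC"] <- (1 - cfr) * (1 - m_acvd)

  p_rec <- rec * sc$sp_mult
  stay <- 1 - p_rec - m
  if (stay < 0) stop("parameter infeasibility in CHRONIC at age ", age,
                     call. = FALSE)
  M["CHRONIC", "ACVD"] <- p_rec
  M["CHRONIC", "NONCVD_DEATH"] <- m
  M["CHRONIC", "CHRONIC"] <- stay

  M["CVD_DEATH", "CVD_DEATH"] <- 1
  M["NONCVD_DEATH", "NONCVD_DEATH"] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("internal consistency error: row sums deviate from 1 by ",
         max(abs(rs - 1)), call. = FALSE)
  }
  M
}

.risk_band_row <- function(labels, age) {
  lo <- .band_lower(labels)
  idx <- findInterval(age, sort(lo))
  if (idx == 0) stop("age ", age, " below the lowest risk band", call. = FALSE)
  labels[order(lo)][idx]
}

# Banded values resolved for a vector of ages (one regex parse per table).
.banded_at_ages <- function(table, ages) {
  lo <- .band_lower(names(table))
  ord <- order(lo)
  idx <- findInterval(ages, lo[ord])
  if (any(idx == 0)) stop("age below the lowest band", call. = FALSE)
  unname(table[ord])[idx]
}

#' Run the closed-cohort simulation
#'
#' Starts the whole cohort in the general population at `start_age` and
#' propagates state occupancy with one-year cycles, rebuilding the
#' age-specific transition matrix each cycle, up to (not including)
#' `end_age`. Cycle `t = 0` is the year lived from `start_age`.
#'
#' @param ps A `cvd_params` object.
#' @param scenario One of [cvd_scenarios()].
#' @param sex `"M"` or `"F"`.
#' @param start_age Starting age (typically 45, 55 or 65).
#' @param end_age Exclusive end age; the default 100 gives a 55-year
#'   horizon from age 45.
#' @return An object of class `cvd_trace`: list with `occupancy` (cycles x 9
#'   matrix, rows summing to 1), `new_acvd_events` and `cvd_deaths` per
#'   cycle, `ages`, and the run labels.
#' @export
run_cohort <- function(ps, scenario, sex, start_age = 45, end_age = 100) {
  sex <- match.arg(sex, c("M", "F"))
  n_cycles <- end_age - start_age
  if (n_cycles < 1) stop("horizon must be at least one cycle", call. = FALSE)
  sc <- .scenario_spec(ps, scenario)

  occ <- matrix(0, n_cycles, 9, dimnames = list(NULL, cvd_states()))
  occ[1, "GEN"] <- 1
  ages <- start_age + seq_len(n_cycles) - 1

  # resolve all banded inputs per age in one pass, then build one matrix
  # per run of ages sharing the same banded values
  ri <- ps$risk_incidence[[sex]]
  ri_lo <- .band_lower(rownames(ri))
  ri_idx <- findInterval(ages, sort(ri_lo))
  if (any(ri_idx == 0)) stop("start age below the lowest risk band",
                             call. = FALSE)
  m_age <- .banded_at_ages(ps$background_mortality[[sex]], ages)
  rec_age <- .banded_at_ages(ps$recurrent_acvd_tp, ages)
  cfr_age <- ps$stroke_weight * .banded_at_ages(ps$cfr_stroke[[sex]], ages) +
    (1 - ps$stroke_weight) * .banded_at_ages(ps$cfr_ihd[[sex]], ages)
  key <- paste(ri_idx, m_age, rec_age, cfr_age)
  mats <- list()
  for (t in seq_len(n_cycles - 1)) {
    M <- mats[[key[t]]]
    if (is.null(M)) {
      M <- .transition_core(ps, sc,
                            inc = ri[order(ri_lo)[ri_idx[t]], ],
                            m = m_age[t], cfr = cfr_age[t],
                            rec = rec_age[t], age = ages[t])
      mats[[key[t]]] <- M
    }
    occ[t + 1, ] <- occ[t, ] %*% M
  }
  cvd_cum <- occ[, "CVD_DEATH"]
  structure(list(
    occupancy = occ,
    ages = ages,
    new_acvd_events = occ[, "ACVD"],
    cvd_deaths = c(0, diff(cvd_cum)),
    start_age = start_age,
    sex = sex,
    scenario = sc$scenario
  ), class = "cvd_trace")
}

#' @export
print.cvd_trace <- function(x, ...) {
  cat("<cvd_trace> ", x$scenario, ", sex ", x$sex, ", ages ",
      min(x$ages), "-", max(x$ages), " (", nrow(x$occupancy),
      " cycles)\n", sep = "")
  invisible(x)
}

#' Flatten a cohort trace to a tidy per-cycle table
#'
#' @param x A `cvd_trace`.
#' @param ... Unused.
#' @return Data.frame with columns `cycle`, `age`, `state`, `occupancy`,
#'   `new_acvd_events`, `cvd_deaths` (the last two repeated across states
#'   within a cycle).
#' @export
as.data.frame.cvd_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  data.frame(
    cycle = rep(seq_len(n) - 1L, times = 9),
    age = rep(x$ages, times = 9),
    state = rep(cvd_states(), each = n),
    occupancy = as.vector(x$occupancy),
    new_acvd_events = rep(x$new_acvd_events, times = 9),
    cvd_deaths = rep(x$cvd_deaths, times = 9),
    stringsAsFactors = FALSE
  )
}

#' Discounted cost and QALYs for one strategy run
#'
#' Runs the cohort and accumulates, per cycle, the utility-weighted
#' occupancy (QALYs) and the scenario's annual state costs plus the
#' per-event acute treatment cost (and productivity loss under the societal
#' perspective), each discounted at the parameter set's annual rate with the
#' first cycle undiscounted. Membership is full-year; no half-cycle
#' correction is applied.
#'
#' @param ps A `cvd_params` object.
#' @param scenario One of [cvd_scenarios()].
#' @param sex `"M"` or `"F"`.
#' @param perspective `"provider"` (direct medical costs) or `"societal"`
#'   (adds productivity loss per acute event).
#' @param start_age,end_age As in [run_cohort()].
#' @return One-row data.frame: `strategy`, `sex`, `perspective`,
#'   `start_age`, `cost`, `qaly`, `lifetime_events`, `lifetime_cvd_deaths`.
#' @export
evaluate_strategy <- function(ps, scenario, sex,
                              perspective = c("provider", "societal"),
                              start_age = 45, end_age = 100) {
  perspective <- match.arg(perspective)
  tr <- run_cohort(ps, scenario, sex, start_age, end_age)
  sc <- .scenario_spec(ps, scenario)
  n <- nrow(tr$occupancy)
  t0 <- if (isTRUE(ps$config$discount_first_cycle)) 1 else 0
  d <- (1 + ps$discount_rate)^(-(seq_len(n) - 1 + t0))

  event_cost <- ps$costs[["acvd"]] +
    if (perspective == "societal") ps$costs[["productivity_loss"]] else 0
  death_cost <- if (perspective == "societal" &&
                    isTRUE(ps$config$productivity_loss_on_death)) {
    ps$costs[["productivity_loss"]]
  } else 0

  per_cycle_cost <- as.vector(tr$occupancy %*% sc$state_cost) +
    tr$new_acvd_events * event_cost +
    tr$occupancy[, "CVD_DEATH"] * death_cost
  u <- ps$utilities[cvd_states()]
  per_cycle_qaly <- as.vector(tr$occupancy %*% u)

  data.frame(
    strategy = sc$scenario,
    sex = sex,
    perspective = perspective,
    start_age = start_age,
    cost = sum(d * per_cycle_cost),
    qaly = sum(d * per_cycle_qaly),
    lifetime_events = sum(tr$new_acvd_events),
    lifetime_cvd_deaths = tr$occupancy[n, "CVD_DEATH"],
    stringsAsFactors = FALSE
  )
}

#' Evaluate several strategies, including the sex-aggregated cohort
#'
#' Runs [evaluate_strategy()] for each scenario and sex and, for
#' `sex = "ALL"`, combines the sex-specific results as a convex combination
#' with weight `ps$male_fraction` on men (the census-based aggregation).
#'
#' @param ps A `cvd_params` object.
#' @param scenarios Character vector of scenarios.
#' @param sexes Subset of `c("M", "F", "ALL")`.
#' @param perspective `"provider"` or `"societal"`.
#' @param start_age,end_age As in [run_cohort()].
#' @return Data.frame, one row per strategy x sex.
#' @export
evaluate_strategies <- function(ps, scenarios = cvd_scenarios(),
                                sexes = "ALL",
                                perspective = c("provider", "societal"),
                                start_age = 45, end_age = 100) {
  perspective <- match.arg(perspective)
  out <- list()
  for (scn in scenarios) {
    res_m <- evaluate_strategy(ps, scn, "M", perspective, start_age, end_age)
    res_f <- evaluate_strategy(ps, scn, "F", perspective, start_age, end_age)
    for (sx in sexes) {
      out[[length(out) + 1]] <- switch(sx,
        M = res_m,
        F = res_f,
        ALL = aggregate_sexes(res_m, res_f, ps$male_fraction),
        stop("unknown sex: ", sx, call. = FALSE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
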
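test_that("transition matrices carry the published flows and structure", {
  ps <- default_parameters()
  M <- build_transition_matrix(ps, "BASE", "M", 50)
  expect_equal(M["GEN", "R10"], 0.0025)
  expect_equal(M["GEN", "R20"], 0.0008)
  expect_equal(M["GEN", "R30"], 0.0006)
  expect_equal(M["GEN", "R40"], 0.0007)
  expect_equal(M["GEN", "NONCVD_DEATH"], 0.0113)
  # primary-prevention multiplier on the treated band
  Mf <- build_transition_matrix(ps, "SC_PP_SP", "F", 50)
  expect_equal(Mf["R20", "ACVD"], 0.0284 * 0.47)
  expect_equal(Mf["R30", "ACVD"], 0.0422 * 0.36)
  # secondary prevention only acts on the recurrent transition
  Msp <- build_transition_matrix(ps, "SP", "M", 50)
  expect_equal(Msp["CHRONIC", "ACVD"], 0.0661 * 0.29)
  expect_equal(Msp["R20", "ACVD"], 0.0284)
  # structural zeros and absorbing rows
  for (scn in cvd_scenarios()) {
    A <- build_transition_matrix(ps, scn, "M", 60)
    expect_equal(rowSums(A), setNames(rep(1, 9), cvd_states()))
    expect_true(all(A >= 0))
    expect_identical(A["GEN", "ACVD"], 0)
    expect_identical(A["R20", "R30"], 0)
    expect_identical(A["CHRONIC", "GEN"], 0)
    expect_identical(A["ACVD", "ACVD"], 0)   # one-cycle tunnel
    expect_equal(A["CVD_DEATH", ], setNames(
      as.numeric(cvd_states() == "CVD_DEATH"), cvd_states()))
    expect_equal(A["NONCVD_DEATH", ], setNames(
      as.numeric(cvd_states() == "NONCVD_DEATH"), cvd_states()))
  }
  # acute row: case fatality first, background mortality among survivors
  cfr <- composite_case_fatality(ps, "M", 60)
  m <- band_lookup(ps$background_mortality$M, 60)
  A <- build_transition_matrix(ps, "BASE", "M", 60)
  expect_equal(A["ACVD", "CVD_DEATH"], cfr)
  expect_equal(A["ACVD", "NONCVD_DEATH"], (1 - cfr) * m)
  expect_equal(A["ACVD", "CHRONIC"], (1 - cfr) * (1 - m))
})

test_that("cohort trace conserves mass and death states absorb", {
  ps <- default_parameters()
  for (scn in c("BASE", "SC_PP_SP")) {
    tr <- run_cohort(ps, scn, "F", 45)
    expect_equal(nrow(tr$occupancy), 55)
    expect_equal(tr$occupancy[1, ], setNames(
      as.numeric(cvd_states() == "GEN"), cvd_states()))
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 55),
                 tolerance = 1e-10)
    expect_true(all(diff(tr$occupancy[, "CVD_DEATH"]) >= 0))
    expect_true(all(diff(tr$occupancy[, "NONCVD_DEATH"]) >= 0))
  }
  expect_error(run_cohort(ps, "BASE", "M", 45, 45), "horizon")
})

test_that("a cohort with no flows stays put; real mortality empties it", {
  ps <- frozen_cohort_params()
  tr <- run_cohort(ps, "BASE", "M", 45)
  expect_true(all(tr$occupancy[, "GEN"] == 1))
  # with published mortality, background deaths alone exceed 95% by age 100
  ps <- default_parameters()
  tr <- run_cohort(ps, "BASE", "M", 45)
  surv_background <- prod(1 - band_lookup(ps$background_mortality$M, 45:98))
  dead <- tr$occupancy[55, "CVD_DEATH"] + tr$occupancy[55, "NONCVD_DEATH"]
  expect_gte(dead, 1 - surv_background - 1e-10)
  expect_gt(dead, 0.95)
})

test_that("three-cycle costs and QALYs match a hand-unrolled computation", {
  ps <- default_parameters()
  for (persp in c("provider", "societal")) {
    got <- evaluate_strategy(ps, "SC_PP_SP", "M", persp, 45, 48)
    occ0 <- as.numeric(cvd_states() == "GEN")
    occ1 <- occ0 %*% build_transition_matrix(ps, "SC_PP_SP", "M", 45)
    occ2 <- occ1 %*% build_transition_matrix(ps, "SC_PP_SP", "M", 46)
    occ <- rbind(occ0, occ1, occ2)
    u <- ps$utilities[cvd_states()]
    d <- 1.03^(-(0:2))
    expect_equal(got$qaly, sum(d * (occ %*% u)), tolerance = 1e-12)
    state_cost <- setNames(numeric(9), cvd_states())
    state_cost[c("GEN", "R10")] <- 9.13
    state_cost["R20"] <- 38.62
    state_cost[c("R30", "R40")] <- 41.11
    state_cost["CHRONIC"] <- 41.28
    ev <- 449.40 + if (persp == "societal") 4360 else 0
    cost <- sum(d * (occ %*% state_cost + occ[, 6] * ev))
    expect_equal(got$cost, cost, tolerance = 1e-12)
  }
})

test_that("null interventions equal the base scenario exactly", {
  ps <- default_parameters()
  ps$effects["sp"] <- 1
  ps$costs["sp"] <- 0
  for (persp in c("provider", "societal")) {
    base <- evaluate_strategy(ps, "BASE", "F", persp)
    sp <- evaluate_strategy(ps, "SP", "F", persp)
    expect_identical(sp$cost, base$cost)
    expect_identical(sp$qaly, base$qaly)
  }
})

test_that("effective prevention never loses QALYs and discounting is
           monotone", {
  ps <- default_parameters()
  base <- evaluate_strategy(ps, "BASE", "M", "provider")
  for (scn in c("SC_PP_SP", "SC_PP", "SP")) {
    expect_gte(evaluate_strategy(ps, scn, "M", "provider")$qaly, base$qaly)
  }
  ps0 <- ps
  ps0$discount_rate <- 0
  ps6 <- ps
  ps6$discount_rate <- 0.06
  r0 <- evaluate_strategy(ps0, "BASE", "M", "provider")
  r3 <- evaluate_strategy(ps, "BASE", "M", "provider")
  r6 <- evaluate_strategy(ps6, "BASE", "M", "provider")
  expect_true(r0$qaly > r3$qaly && r3$qaly > r6$qaly)
  expect_true(r0$cost > r3$cost && r3$cost > r6$cost)
})

test_that("the discounted QALY annuity matches the geometric closed form", {
  ps <- frozen_cohort_params(gen_utility = 1)
  got <- evaluate_strategy(ps, "BASE", "M", "provider", 45, 100)
  v <- 1 / 1.03
  closed_form <- (1 - v^55) / (1 - v)
  expect_equal(got$qaly, closed_form, tolerance = 1e-12)
  expect_equal(round(got$qaly, 2), 27.58)
  # first cycle undiscounted by default; the configurable alternative
  # discounts every cycle once
  ps$config$discount_first_cycle <- TRUE
  got2 <- evaluate_strategy(ps, "BASE", "M", "provider", 45, 100)
  expect_equal(got2$qaly, closed_form * v, tolerance = 1e-12)
})

test_that("later starting ages accumulate fewer QALYs", {
  ps <- default_parameters()
  q <- vapply(c(45, 55, 65), function(a) {
    evaluate_strategy(ps, "SC_PP_SP", "M", "provider", a)$qaly
  }, numeric(1))
  expect_true(q[1] > q[2] && q[2] > q[3])
})

test_that("the tidy trace export is consistent with the trace", {
  ps <- default_parameters()
  tr <- run_cohort(ps, "SP", "M", 65, 70)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 5 * 9)
  expect_equal(sum(df$occupancy), 5, tolerance = 1e-10)
  expect_equal(df$age[df$cycle == 0][1], 65)
  expect_equal(df$occupancy[df$state == "ACVD"],
               unname(tr$new_acvd_events))
})
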
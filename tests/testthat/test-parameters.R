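test_that("cumulative-to-annual conversion reproduces the published annual
           acute-CVD probabilities from the risk-band midpoints", {
  # band midpoints 15/25/35/45% over 10 years -> printed annual TPs
  expect_equal(round(annual_prob_from_cumulative(0.15, 10), 4), 0.0161)
  expect_equal(round(annual_prob_from_cumulative(0.25, 10), 4), 0.0284)
  expect_equal(round(annual_prob_from_cumulative(0.35, 10), 4), 0.0422)
  expect_equal(round(annual_prob_from_cumulative(0.45, 10), 4), 0.0580)
  expect_identical(annual_prob_from_cumulative(0, 10), 0)
})

test_that("conversion is monotone, bounded and inverts exactly", {
  p <- seq(0.01, 0.95, by = 0.07)
  a10 <- annual_prob_from_cumulative(p, 10)
  expect_true(all(diff(a10) > 0))            # increasing in p_cum
  expect_true(all(a10 <= p & a10 >= 0))
  a20 <- annual_prob_from_cumulative(p, 20)
  expect_true(all(a20 < a10))                # decreasing in years
  expect_equal(1 - (1 - a10)^10, p, tolerance = 1e-12)
  expect_error(annual_prob_from_cumulative(1, 10), "probability")
  expect_error(annual_prob_from_cumulative(0.5, 0.5), ">= 1")
})

test_that("relative risks combine multiplicatively", {
  expect_identical(combine_relative_risks(numeric(0)), 1)
  expect_equal(combine_relative_risks(c(0.5, 0.5)), 0.25)
  # the aspirin multiplier implied by the published 0.47 -> 0.36 step
  expect_equal(round(combine_relative_risks(c(0.47, 0.766)), 2), 0.36)
  expect_error(combine_relative_risks(c(0.5, 0)), "positive")
})

test_that("banded lookup uses half-open bands with an open-ended top", {
  ps <- default_parameters()
  expect_equal(band_lookup(ps$background_mortality$M, 54), 0.0113)
  expect_equal(band_lookup(ps$background_mortality$M, 55), 0.0169)
  expect_equal(band_lookup(ps$background_mortality$F, 90), 0.1830)
  expect_equal(band_lookup(ps$background_mortality$F, 120), 0.1830)
  expect_error(band_lookup(ps$background_mortality$M, 30), "below")
})

test_that("composite case fatality is the stroke-weighted convex mix", {
  ps <- default_parameters()
  ps$stroke_weight <- 1
  expect_equal(composite_case_fatality(ps, "M", 55), 0.2154)
  ps$stroke_weight <- 0
  expect_equal(composite_case_fatality(ps, "M", 55), 0.6128)
  ps$stroke_weight <- 0.5
  expect_equal(composite_case_fatality(ps, "M", 55), (0.2154 + 0.6128) / 2)
  # convex combination stays between the two inputs at any weight and age
  for (w in c(0.1, 0.3, 0.9)) {
    ps$stroke_weight <- w
    for (age in c(42, 57, 66, 74, 88)) {
      for (sex in c("M", "F")) {
        cf <- composite_case_fatality(ps, sex, age)
        lohi <- range(band_lookup(ps$cfr_stroke[[sex]], age),
                      band_lookup(ps$cfr_ihd[[sex]], age))
        expect_true(cf >= lohi[1] && cf <= lohi[2])
      }
    }
  }
  expect_error(composite_case_fatality(ps, "M", 30), "below")
})

test_that("moment matching hits the requested mean and sd analytically", {
  p <- moment_match("gamma", 9.13, 9.13)
  expect_equal(p$shape, 1)
  expect_equal(p$scale, 9.13)
  p <- moment_match("beta", 0.5, 0.1)
  expect_equal(p$alpha, 12)
  expect_equal(p$beta, 12)
  # analytic round-trip across families and feasible moments
  for (m in c(0.1, 0.47, 0.93)) {
    for (se_rel in c(0.05, 0.1, 0.3)) {
      se <- se_rel * m
      g <- moment_match("gamma", m, se)
      expect_equal(g$shape * g$scale, m, tolerance = 1e-9)
      expect_equal(sqrt(g$shape) * g$scale, se, tolerance = 1e-9)
      if (se^2 < m * (1 - m)) {
        b <- moment_match("beta", m, se)
        expect_equal(b$alpha / (b$alpha + b$beta), m, tolerance = 1e-9)
        expect_equal(sqrt(b$alpha * b$beta /
                            ((b$alpha + b$beta)^2 *
                               (b$alpha + b$beta + 1))),
                     se, tolerance = 1e-9)
      } else {
        expect_error(moment_match("beta", m, se), "infeasible")
      }
      l <- moment_match("lognormal", m, se)
      expect_equal(exp(l$meanlog + l$sdlog^2 / 2), m, tolerance = 1e-9)
      expect_equal(sqrt((exp(l$sdlog^2) - 1)) *
                     exp(l$meanlog + l$sdlog^2 / 2), se, tolerance = 1e-9)
    }
  }
  expect_error(moment_match("beta", 0.5, 0.6), "infeasible")
  expect_error(moment_match("beta", 1.2, 0.1), "mean < 1")
})

test_that("the packaged default set reproduces the published tables", {
  ps <- default_parameters()
  # risk-band incidence (percent, men then women; bands 45-54/55-64/65+)
  expect_equal(100 * as.vector(t(ps$risk_incidence$M)),
               c(0.25, 0.08, 0.06, 0.07,
                 1.12, 0.57, 0.35, 0.48,
                 1.81, 0.01, 0.49, 0.37))
  expect_equal(100 * as.vector(t(ps$risk_incidence$F)),
               c(0.19, 0.12, 0.01, 0.05,
                 1.52, 0.49, 0.11, 0.47,
                 0.34, 0.89, 0.55, 0.33))
  expect_equal(unname(ps$acvd_tp), c(0.0161, 0.0284, 0.0422, 0.0580))
  expect_equal(unname(ps$recurrent_acvd_tp), c(0.0661, 0.0684, 0.1088))
  expect_equal(100 * unname(ps$background_mortality$M),
               c(0.72, 1.13, 1.69, 2.61, 3.83, 5.82, 8.61, 13.13, 21.73))
  expect_equal(100 * unname(ps$background_mortality$F),
               c(0.40, 0.60, 0.87, 1.39, 2.21, 6.17, 6.17, 10.21, 18.30))
  expect_equal(100 * unname(ps$cfr_stroke$M),
               c(26.30, 21.54, 21.61, 27.66, 38.11))
  expect_equal(100 * unname(ps$cfr_stroke$F),
               c(23.22, 23.37, 24.40, 29.40, 37.56))
  expect_equal(100 * unname(ps$cfr_ihd$M),
               c(60.84, 61.28, 63.77, 66.96, 71.07))
  expect_equal(100 * unname(ps$cfr_ihd$F),
               c(70.94, 71.30, 73.07, 75.18, 78.50))
  expect_equal(unname(ps$costs),
               c(9.13, 38.62, 41.11, 41.28, 449.40, 4360.00))
  expect_equal(unname(ps$utilities),
               c(0.93, 0.92, 0.91, 0.87, 0.85, 0.47, 0.64, 0, 0))
  expect_equal(unname(ps$effects), c(0.47, 0.36, 0.29))
  expect_equal(ps$discount_rate, 0.03)
  expect_equal(unname(ps$wtp_thresholds), c(1400.2, 4200.6))
})

test_that("validation rejects out-of-range and inconsistent inputs", {
  ps <- default_parameters()
  bad <- ps
  bad$utilities["GEN"] <- 1.2
  expect_error(validate_parameters(bad), "utilities")
  bad <- ps
  bad$utilities["CVD_DEATH"] <- 0.1
  expect_error(validate_parameters(bad), "death-state")
  bad <- ps
  bad$acvd_tp["R30"] <- 0.9   # breaks strict ordering (R40 = 0.058)
  expect_error(validate_parameters(bad), "increasing")
  bad <- ps
  bad$effects["sp"] <- 0
  expect_error(validate_parameters(bad), "effects")
  bad <- ps
  bad$risk_incidence$M["45-54", "R10"] <- 0.999
  expect_error(validate_parameters(bad), "incidence")
  expect_false(isTRUE(validate_parameters(bad, quiet = TRUE)))
})

test_that("parameter files round-trip through YAML and tidy CSV", {
  ps <- default_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(ps, path)
  back <- load_parameters(path)
  expect_identical(unclass(back), unclass(ps))
  # percent dialect
  write_parameters(ps, path, percent = TRUE)
  back_pct <- load_parameters(path)
  expect_equal(unclass(back_pct), unclass(ps), tolerance = 1e-12)
  # tidy table round-trip
  tidy <- parameters_to_tidy(ps)
  rebuilt <- parameters_from_tidy(tidy)
  expect_equal(unclass(rebuilt), unclass(ps), tolerance = 1e-15)
  # schema violations are descriptive
  tidy_bad <- tidy
  tidy_bad$value[tidy_bad$section == "utilities" &
                   tidy_bad$name == "GEN"] <- 1.2
  expect_error(parameters_from_tidy(tidy_bad), "utilities")
  expect_error(load_parameters("no/such/file.yaml"), "no such")
})
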
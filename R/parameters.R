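# Parameter model: typed parameter set, validation, banded lookups, and the
# derivation operations applied to raw inputs (cumulative-to-annual risk
# conversion, relative-risk combination, composite case fatality,
# moment matching for PSA distributions).

#' Convert a cumulative multi-year risk to an annual transition probability
#'
#' Assumes a constant annual hazard over the period, so that
#' \eqn{p_{annual} = 1 - (1 - p_{cum})^{1/years}}. This is the standard
#' conversion used to turn a 10-year cardiovascular risk (e.g. 15\% for the
#' 10-19.9\% risk band midpoint) into the per-cycle probability of an acute
#' event in a one-year-cycle Markov model.
#'
#' @param p_cum Cumulative probability over `years` years, in `[0, 1)`.
#' @param years Length of the period in years (>= 1).
#' @return Annual probability, in `[0, p_cum]`.
#' @examples
#' annual_prob_from_cumulative(0.15, 10)  # ~0.0161
#' @export
annual_prob_from_cumulative <- function(p_cum, years) {
  if (!is.numeric(p_cum) || any(p_cum < 0) || any(p_cum >= 1)) {
    stop("`p_cum` must be a probability in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(years) || any(years < 1)) {
    stop("`years` must be >= 1", call. = FALSE)
  }
  1 - (1 - p_cum)^(1 / years)
}

#' Combine independent relative risks into an overall treatment effect
#'
#' Drug effects are assumed independent, so the overall effect of a package
#' of drugs is the product of the individual relative risks (each a
#' treated-to-untreated risk multiplier in (0, 1.5]). An empty set of drugs
#' has no effect (returns 1).
#'
#' @param rr_values Numeric vector of relative risks.
#' @return The product of `rr_values` (1 for an empty vector).
#' @export
combine_relative_risks <- function(rr_values) {
  if (length(rr_values) == 0) return(1)
  if (!is.numeric(rr_values) || any(rr_values <= 0)) {
    stop("relative risks must be positive", call. = FALSE)
  }
  if (any(rr_values > 1.5)) {
    stop("relative risks above 1.5 are not supported", call. = FALSE)
  }
  prod(rr_values)
}

# Parse band labels like "45-54", ">=85", "85+" into lower bounds.
.band_lower <- function(labels) {
  lo <- suppressWarnings(as.numeric(sub("^([0-9]+).*$", "\\1", labels)))
  if (any(is.na(lo))) stop("unparseable band label(s): ",
                           paste(labels[is.na(lo)], collapse = ", "),
                           call. = FALSE)
  lo
}

#' Look up the value of the age band containing an age
#'
#' Bands are encoded as a named numeric vector whose names give the band
#' lower bounds (e.g. `c("45-49" = 0.0072, ..., "85+" = 0.2173)`). Bands are
#' half-open `[lo, next lo)`; the last band is open-ended.
#'
#' @param table Named numeric vector of banded values.
#' @param age Age in years.
#' @return The value of the unique band containing `age`.
#' @export
band_lookup <- function(table, age) {
  lo <- .band_lower(names(table))
  ord <- order(lo)
  idx <- findInterval(age, lo[ord])
  if (any(idx == 0)) {
    stop("age ", paste(age[idx == 0], collapse = ", "),
         " below the lowest band (", min(lo), ")", call. = FALSE)
  }
  unname(table[ord][idx])
}

#' Composite acute-CVD case fatality for a given sex and age
#'
#' Acute CVD pools acute stroke and acute ischaemic heart disease; the
#' per-event probability of death is the stroke-share-weighted mean of the
#' two age- and sex-specific case fatality rates:
#' `w * CFR_stroke + (1 - w) * CFR_IHD`.
#'
#' @param ps A parameter set (see [default_parameters()]).
#' @param sex `"M"` or `"F"`.
#' @param age Age in years (>= 40, the youngest case-fatality band).
#' @return Probability of death per acute event.
#' @export
composite_case_fatality <- function(ps, sex, age) {
  sex <- match.arg(sex, c("M", "F"))
  w <- ps$stroke_weight
  w * band_lookup(ps$cfr_stroke[[sex]], age) +
    (1 - w) * band_lookup(ps$cfr_ihd[[sex]], age)
}

#' Moment-match a gamma, beta or lognormal distribution
#'
#' Returns the natural parameters of the requested family such that its mean
#' and standard deviation equal `mean` and `se`. Used to build the PSA
#' sampling distributions from the published means and relative standard
#' errors (gamma for costs, beta for utilities and transition probabilities,
#' lognormal for treatment effects).
#'
#' @param family `"gamma"`, `"beta"` or `"lognormal"`.
#' @param mean Target mean (> 0; for beta also < 1).
#' @param se Target standard deviation (> 0).
#' @return Named list of distribution parameters: `shape`/`scale` (gamma),
#'   `alpha`/`beta` (beta) or `meanlog`/`sdlog` (lognormal).
#' @export
moment_match <- function(family, mean, se) {
  family <- match.arg(family, c("gamma", "beta", "lognormal"))
  if (!is.numeric(mean) || mean <= 0) stop("`mean` must be > 0", call. = FALSE)
  if (!is.numeric(se) || se <= 0) stop("`se` must be > 0", call. = FALSE)
  v <- se^2
  switch(family,
    gamma = list(shape = (mean / se)^2, scale = v / mean),
    beta = {
      if (mean >= 1) stop("beta requires mean < 1", call. = FALSE)
      if (v >= mean * (1 - mean)) {
        stop("infeasible moments for beta: variance ", v,
             " >= mean*(1-mean) = ", mean * (1 - mean), call. = FALSE)
      }
      nu <- mean * (1 - mean) / v - 1
      list(alpha = mean * nu, beta = (1 - mean) * nu)
    },
    lognormal = {
      sdlog2 <- log(1 + v / mean^2)
      list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
    }
  )
}

# ---------------------------------------------------------------------------
# Default parameter set (published Myanmar inputs)

# percent -> decimal via the shortest decimal representation, so the stored
# value is the same double a plain decimal literal (and the YAML loader)
# would produce
.pct <- function(x) as.numeric(sprintf("%.10g", x / 100))

.default_parameter_list <- function() {
  risk_bands <- c("45-54", "55-64", "65+")
  risk_cats <- c("R10", "R20", "R30", "R40")
  ri_m <- matrix(.pct(c(
    0.25, 0.08, 0.06, 0.07,
    1.12, 0.57, 0.35, 0.48,
    1.81, 0.01, 0.49, 0.37)), nrow = 3, byrow = TRUE,
    dimnames = list(risk_bands, risk_cats))
  ri_f <- matrix(.pct(c(
    0.19, 0.12, 0.01, 0.05,
    1.52, 0.49, 0.11, 0.47,
    0.34, 0.89, 0.55, 0.33)), nrow = 3, byrow = TRUE,
    dimnames = list(risk_bands, risk_cats))

  mort_bands <- c("45-49", "50-54", "55-59", "60-64", "65-69",
                  "70-74", "75-79", "80-84", "85+")
  mort_m <- .pct(c(0.72, 1.13, 1.69, 2.61, 3.83, 5.82, 8.61, 13.13, 21.73))
  mort_f <- .pct(c(0.40, 0.60, 0.87, 1.39, 2.21, 6.17, 6.17, 10.21, 18.30))
  names(mort_m) <- names(mort_f) <- mort_bands

  cfr_bands <- c("40-49", "50-59", "60-69", "70-79", "80+")
  cfr_stroke_m <- .pct(c(26.30, 21.54, 21.61, 27.66, 38.11))
  cfr_stroke_f <- .pct(c(23.22, 23.37, 24.40, 29.40, 37.56))
  cfr_ihd_m <- .pct(c(60.84, 61.28, 63.77, 66.96, 71.07))
  cfr_ihd_f <- .pct(c(70.94, 71.30, 73.07, 75.18, 78.50))
  names(cfr_stroke_m) <- names(cfr_stroke_f) <- cfr_bands
  names(cfr_ihd_m) <- names(cfr_ihd_f) <- cfr_bands

  list(
    risk_incidence = list(M = ri_m, F = ri_f),
    acvd_tp = c(R10 = 0.0161, R20 = 0.0284, R30 = 0.0422, R40 = 0.0580),
    recurrent_acvd_tp = c("45-54" = 0.0661, "55-64" = 0.0684,
                          "65+" = 0.1088),
    background_mortality = list(M = mort_m, F = mort_f),
    cfr_stroke = list(M = cfr_stroke_m, F = cfr_stroke_f),
    cfr_ihd = list(M = cfr_ihd_m, F = cfr_ihd_f),
    stroke_weight = 0.3,
    costs = c(screening = 9.13, pp_mid = 38.62, pp_high = 41.11,
              sp = 41.28, acvd = 449.40, productivity_loss = 4360.00),
    utilities = c(GEN = 0.93, R10 = 0.92, R20 = 0.91, R30 = 0.87,
                  R40 = 0.85, ACVD = 0.47, CHRONIC = 0.64,
                  CVD_DEATH = 0, NONCVD_DEATH = 0),
    effects = c(pp_mid = 0.47, pp_high = 0.36, sp = 0.29),
    discount_rate = 0.03,
    wtp_thresholds = c(gdp1 = 1400.2, gdp3 = 4200.6),
    male_fraction = 0.48,
    psa_spec = list(se_rel_cost = 1.0, se_rel_utility = 0.1,
                    se_rel_effect = 0.1, se_rel_tp = 0.1),
    config = list(effect_is_multiplier = TRUE,
                  discount_first_cycle = FALSE,
                  acvd_background_mortality = TRUE,
                  productivity_loss_on_death = FALSE)
  )
}

#' The packaged default parameter set
#'
#' The published Myanmar inputs: annual transition probabilities into the
#' four 10-year CVD risk bands by sex and age band, annual acute-CVD
#' probabilities per risk band, recurrent-event probabilities, background
#' mortality, stroke and ischaemic-heart-disease case fatality rates, costs
#' (US$, 2015-2021 price base), state utilities, treatment-effect relative
#' risks, the 3\% discount rate and the 1x/3x GDP-per-capita
#' willingness-to-pay thresholds. All probabilities are stored as decimals.
#'
#' @return A validated object of class `cvd_params`.
#' @export
default_parameters <- function() {
  ps <- structure(.default_parameter_list(), class = "cvd_params")
  validate_parameters(ps)
}

#' Validate a parameter set
#'
#' Checks ranges (probabilities and utilities in `[0,1]`, costs and discount
#' rate non-negative, treatment effects in `(0,1]`), structural constraints
#' (acute-CVD risk strictly increasing across risk bands, death-state
#' utilities exactly zero), and joint feasibility (per sex and age band, the
#' total annual flow out of the general population -- risk-band incidence
#' plus background mortality -- stays below 1).
#'
#' @param ps A `cvd_params` object (or plain list with the same fields).
#' @param quiet If `TRUE`, return `FALSE` instead of erroring.
#' @return `ps` invisibly (or `TRUE`/`FALSE` when `quiet = TRUE`).
#' @export
validate_parameters <- function(ps, quiet = FALSE) {
  fail <- function(...) {
    if (quiet) return(structure(FALSE, msg = paste0(...)))
    stop(..., call. = FALSE)
  }
  required <- c("risk_incidence", "acvd_tp", "recurrent_acvd_tp",
                "background_mortality", "cfr_stroke", "cfr_ihd",
                "stroke_weight", "costs", "utilities", "effects",
                "discount_rate", "wtp_thresholds", "male_fraction",
                "psa_spec", "config")
  missing <- setdiff(required, names(ps))
  if (length(missing)) return(fail("missing field(s): ",
                                   paste(missing, collapse = ", ")))

  prob01 <- function(x, field) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      fail("field `", field, "` must lie in [0, 1]")
    else TRUE
  }
  for (sex in c("M", "F")) {
    r <- prob01(ps$risk_incidence[[sex]], paste0("risk_incidence$", sex))
    if (!isTRUE(r)) return(r)
    r <- prob01(ps$background_mortality[[sex]],
                paste0("background_mortality$", sex))
    if (!isTRUE(r)) return(r)
    r <- prob01(ps$cfr_stroke[[sex]], paste0("cfr_stroke$", sex))
    if (!isTRUE(r)) return(r)
    r <- prob01(ps$cfr_ihd[[sex]], paste0("cfr_ihd$", sex))
    if (!isTRUE(r)) return(r)
  }
  for (f in c("acvd_tp", "recurrent_acvd_tp", "utilities",
              "stroke_weight", "male_fraction")) {
    r <- prob01(ps[[f]], f)
    if (!isTRUE(r)) return(r)
  }
  if (any(ps$costs < 0)) return(fail("field `costs` must be >= 0"))
  if (ps$discount_rate < 0) return(fail("field `discount_rate` must be >= 0"))
  if (any(ps$effects <= 0) || any(ps$effects > 1))
    return(fail("field `effects` must lie in (0, 1]"))
  if (any(diff(ps$acvd_tp[c("R10", "R20", "R30", "R40")]) <= 0))
    return(fail("field `acvd_tp` must be strictly increasing across ",
                "R10 < R20 < R30 < R40"))
  if (any(ps$utilities[c("CVD_DEATH", "NONCVD_DEATH")] != 0))
    return(fail("field `utilities`: death-state utilities must be exactly 0"))

  # joint feasibility of the general-population row at every model age
  for (sex in c("M", "F")) {
    ri <- ps$risk_incidence[[sex]]
    for (band in rownames(ri)) {
      lo <- .band_lower(band)
      hi <- if (band == rownames(ri)[nrow(ri)]) 99 else
        .band_lower(rownames(ri)[which(rownames(ri) == band) + 1]) - 1
      for (age in c(lo, hi)) {
        m <- band_lookup(ps$background_mortality[[sex]], age)
        if (sum(ri[band, ]) >= 1 - m)
          return(fail("risk_incidence$", sex, " band ", band,
                      ": total incidence + background mortality >= 1"))
      }
    }
  }
  if (quiet) return(TRUE)
  invisible(ps)
}

#' @export
print.cvd_params <- function(x, ...) {
  cat("<cvd_params>\n")
  cat("  discount rate:", x$discount_rate,
      " stroke weight:", x$stroke_weight,
      " male fraction:", x$male_fraction, "\n")
  cat("  costs (US$):",
      paste(names(x$costs), x$costs, sep = "=", collapse = ", "), "\n")
  cat("  effects (RR):",
      paste(names(x$effects), x$effects, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parameter file I/O (YAML schema, version 1; tidy CSV import/export)

.matrix_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(out) <- rownames(m)
  out
}

.list_to_matrix <- function(l) {
  rows <- names(l)
  cols <- names(l[[1]])
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (r in rows) m[r, ] <- unlist(l[[r]])[cols]
  m
}

#' Write a parameter set to a YAML file
#'
#' @param ps A `cvd_params` object.
#' @param path Output file path.
#' @param percent If `TRUE`, write probabilities as percentages and set the
#'   `percent: true` dialect flag in the file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path, percent = FALSE) {
  scale <- if (percent) 100 else 1
  doc <- list(
    schema = "cvdprev-params",
    version = 1L,
    percent = percent,
    risk_incidence = lapply(ps$risk_incidence,
                            function(m) .matrix_to_list(m * scale)),
    acvd_tp = as.list(ps$acvd_tp * scale),
    recurrent_acvd_tp = as.list(ps$recurrent_acvd_tp * scale),
    background_mortality = lapply(ps$background_mortality,
                                  function(v) as.list(v * scale)),
    cfr_stroke = lapply(ps$cfr_stroke, function(v) as.list(v * scale)),
    cfr_ihd = lapply(ps$cfr_ihd, function(v) as.list(v * scale)),
    stroke_weight = ps$stroke_weight,
    costs = as.list(ps$costs),
    utilities = as.list(ps$utilities),
    effects = as.list(ps$effects),
    discount_rate = ps$discount_rate,
    wtp_thresholds = as.list(ps$wtp_thresholds),
    male_fraction = ps$male_fraction,
    psa_spec = ps$psa_spec,
    config = ps$config
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Load a parameter set from a YAML file or the packaged default
#'
#' @param source A file path, or `"default"` for the packaged published set.
#' @return A validated `cvd_params` object.
#' @export
load_parameters <- function(source = "default") {
  if (identical(source, "default")) return(default_parameters())
  if (!file.exists(source)) stop("no such parameter file: ", source,
                                 call. = FALSE)
  doc <- yaml::read_yaml(source)
  if (!identical(doc$schema, "cvdprev-params")) {
    stop("not a cvdprev parameter file (missing `schema: cvdprev-params`)",
         call. = FALSE)
  }
  scale <- if (isTRUE(doc$percent)) 1 / 100 else 1
  unlist_named <- function(l) {
    v <- vapply(l, as.numeric, numeric(1))
    names(v) <- names(l)
    v
  }
  ps <- structure(list(
    risk_incidence = lapply(doc$risk_incidence,
                            function(l) .list_to_matrix(l) * scale),
    acvd_tp = unlist_named(doc$acvd_tp) * scale,
    recurrent_acvd_tp = unlist_named(doc$recurrent_acvd_tp) * scale,
    background_mortality = lapply(doc$background_mortality,
                                  function(l) unlist_named(l) * scale),
    cfr_stroke = lapply(doc$cfr_stroke, function(l) unlist_named(l) * scale),
    cfr_ihd = lapply(doc$cfr_ihd, function(l) unlist_named(l) * scale),
    stroke_weight = as.numeric(doc$stroke_weight),
    costs = unlist_named(doc$costs),
    utilities = unlist_named(doc$utilities),
    effects = unlist_named(doc$effects),
    discount_rate = as.numeric(doc$discount_rate),
    wtp_thresholds = unlist_named(doc$wtp_thresholds),
    male_fraction = as.numeric(doc$male_fraction),
    psa_spec = lapply(doc$psa_spec, as.numeric),
    config = doc$config
  ), class = "cvd_params")
  validate_parameters(ps)
}

#' Export a parameter set as one tidy table
#'
#' One row per scalar: `(section, sex, band, name, value)`, suitable for
#' CSV export with [utils::write.csv()]. [parameters_from_tidy()] inverts it.
#'
#' @param ps A `cvd_params` object.
#' @return A data.frame.
#' @export
parameters_to_tidy <- function(ps) {
  rows <- list()
  add <- function(section, sex, band, name, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      section = section, sex = sex, band = band, name = name,
      value = value, stringsAsFactors = FALSE)
  }
  for (sex in c("M", "F")) {
    ri <- ps$risk_incidence[[sex]]
    for (b in rownames(ri)) for (k in colnames(ri))
      add("risk_incidence", sex, b, k, ri[b, k])
    for (b in names(ps$background_mortality[[sex]]))
      add("background_mortality", sex, b, "", ps$background_mortality[[sex]][b])
    for (b in names(ps$cfr_stroke[[sex]]))
      add("cfr_stroke", sex, b, "", ps$cfr_stroke[[sex]][b])
    for (b in names(ps$cfr_ihd[[sex]]))
      add("cfr_ihd", sex, b, "", ps$cfr_ihd[[sex]][b])
  }
  for (k in names(ps$acvd_tp)) add("acvd_tp", "", "", k, ps$acvd_tp[k])
  for (b in names(ps$recurrent_acvd_tp))
    add("recurrent_acvd_tp", "", b, "", ps$recurrent_acvd_tp[b])
  for (k in names(ps$costs)) add("costs", "", "", k, ps$costs[k])
  for (k in names(ps$utilities)) add("utilities", "", "", k, ps$utilities[k])
  for (k in names(ps$effects)) add("effects", "", "", k, ps$effects[k])
  add("scalar", "", "", "stroke_weight", ps$stroke_weight)
  add("scalar", "", "", "discount_rate", ps$discount_rate)
  add("scalar", "", "", "male_fraction", ps$male_fraction)
  for (k in names(ps$wtp_thresholds))
    add("wtp_thresholds", "", "", k, ps$wtp_thresholds[k])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild a parameter set from a tidy table
#'
#' Inverse of [parameters_to_tidy()]. Sections absent from the table keep
#' their values from `base` (default: the packaged set), so a tidy CSV can
#' carry a partial override.
#'
#' @param df Data.frame with columns `section, sex, band, name, value`.
#' @param base Parameter set supplying any fields not present in `df`.
#' @return A validated `cvd_params` object.
#' @export
parameters_from_tidy <- function(df, base = default_parameters()) {
  ps <- unclass(base)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    v <- as.numeric(r$value)
    switch(as.character(r$section),
      risk_incidence = ps$risk_incidence[[r$sex]][r$band, r$name] <- v,
      background_mortality = ps$background_mortality[[r$sex]][r$band] <- v,
      cfr_stroke = ps$cfr_stroke[[r$sex]][r$band] <- v,
      cfr_ihd = ps$cfr_ihd[[r$sex]][r$band] <- v,
      acvd_tp = ps$acvd_tp[r$name] <- v,
      recurrent_acvd_tp = ps$recurrent_acvd_tp[r$band] <- v,
      costs = ps$costs[r$name] <- v,
      utilities = ps$utilities[r$name] <- v,
      effects = ps$effects[r$name] <- v,
      wtp_thresholds = ps$wtp_thresholds[r$name] <- v,
      scalar = ps[[r$name]] <- v,
      stop("unknown section: ", r$section, call. = FALSE)
    )
  }
  validate_parameters(structure(ps, class = "cvd_params"))
}
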
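# Synthetic-data generators: randomized-but-valid parameter sets for
# property testing and census-like population tables for the budget impact
# analysis. Kept independent of the PSA sampling machinery on purpose: the
# perturbation here is multiplicative uniform, not distributional, so these
# fixtures can exercise the PSA code without sharing its assumptions.

#' Randomly perturbed but valid parameter set
#'
#' Each stochastic parameter of the packaged default set (or of `base`) is
#' multiplied by an independent uniform factor in `[1 - scale, 1 + scale]`;
#' values that would leave `[0, 1]` are resampled, and the whole set is
#' re-validated (and redrawn on a joint-invariant breach, up to 100 times).
#' `scale = 0` reproduces `base` exactly. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param scale Relative perturbation half-width in `[0, 0.5]`.
#' @param base Parameter set to perturb.
#' @return A validated `cvd_params` object.
#' @export
perturbed_parameters <- function(seed = 1, scale = 0.1,
                                 base = default_parameters()) {
  if (scale < 0 || scale > 0.5) {
    stop("`scale` must lie in [0, 0.5]", call. = FALSE)
  }
  if (scale == 0) return(base)
  set.seed(seed)
  jitter_prob <- function(x) {
    vapply(x, function(v) {
      if (v == 0) return(0)
      for (k in seq_len(100)) {
        out <- v * stats::runif(1, 1 - scale, 1 + scale)
        if (out <= 1) return(out)
      }
      stop("could not keep a perturbed probability within [0, 1]",
           call. = FALSE)
    }, numeric(1))
  }
  for (attempt in seq_len(100)) {
    draw <- unclass(base)
    for (sex in c("M", "F")) {
      draw$risk_incidence[[sex]][] <- jitter_prob(base$risk_incidence[[sex]])
      draw$background_mortality[[sex]][] <-
        jitter_prob(base$background_mortality[[sex]])
      draw$cfr_stroke[[sex]][] <- jitter_prob(base$cfr_stroke[[sex]])
      draw$cfr_ihd[[sex]][] <- jitter_prob(base$cfr_ihd[[sex]])
    }
    # a shared factor preserves the strict across-band ordering of the
    # acute-event probabilities
    repeat {
      f <- stats::runif(1, 1 - scale, 1 + scale)
      tp <- base$acvd_tp * f
      if (all(tp <= 1)) break
    }
    draw$acvd_tp[] <- tp
    draw$recurrent_acvd_tp[] <- jitter_prob(base$recurrent_acvd_tp)
    draw$costs[] <- base$costs *
      stats::runif(length(base$costs), 1 - scale, 1 + scale)
    live <- setdiff(names(base$utilities), c("CVD_DEATH", "NONCVD_DEATH"))
    draw$utilities[live] <- jitter_prob(base$utilities[live])
    repeat {
      eff <- base$effects *
        stats::runif(length(base$effects), 1 - scale, 1 + scale)
      if (all(eff <= 1)) break
    }
    draw$effects[] <- eff
    out <- structure(draw, class = "cvd_params")
    if (isTRUE(validate_parameters(out, quiet = TRUE))) return(out)
  }
  stop("could not generate a valid parameter set in 100 attempts",
       call. = FALSE)
}

#' Generate a census-like population table
#'
#' Persons by sex and 5-year age band from 45-49 to 85+, decreasing
#' geometrically with age (`decay` per band), split between sexes by
#' `male_fraction`, with largest-remainder rounding so that the printed
#' total and the sex totals match `total` exactly.
#'
#' @param total Total persons aged >= 45 (> 0).
#' @param male_fraction Male share in `[0, 1]`.
#' @param decay Per-band geometric decay factor in `(0, 1)`.
#' @param seed Accepted for interface symmetry with the other generators;
#'   the table is fully determined by the shape parameters.
#' @return Data.frame with columns `sex`, `age_band`, `persons`.
#' @export
generate_population <- function(total, male_fraction = 0.48, decay = 0.78,
                                seed = 1) {
  if (!is.numeric(total) || total <= 0) {
    stop("`total` must be > 0", call. = FALSE)
  }
  if (decay <= 0 || decay >= 1) {
    stop("`decay` must lie in (0, 1)", call. = FALSE)
  }
  bands <- c("45-49", "50-54", "55-59", "60-64", "65-69",
             "70-74", "75-79", "80-84", "85+")
  w <- decay^(seq_along(bands) - 1)
  sex_totals <- c(M = round(total * male_fraction))
  sex_totals["F"] <- total - sex_totals[["M"]]
  largest_remainder <- function(n, weights) {
    raw <- n * weights / sum(weights)
    base <- floor(raw)
    short <- n - sum(base)
    if (short > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
      base[extra] <- base[extra] + 1
    }
    base
  }
  out <- do.call(rbind, lapply(c("M", "F"), function(sx) {
    data.frame(sex = sx, age_band = bands,
               persons = largest_remainder(sex_totals[[sx]], w),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
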
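# Shared test helpers: independent oracles and fixture builders.

# Parameter set with no mortality and no disease flow: the whole cohort
# stays in the general population. Used for closed-form annuity checks.
frozen_cohort_params <- function(gen_utility = 1) {
  ps <- default_parameters()
  for (sex in c("M", "F")) {
    ps$risk_incidence[[sex]][] <- 0
    ps$background_mortality[[sex]][] <- 0
  }
  ps$acvd_tp[] <- c(0, 1e-12, 2e-12, 3e-12)  # keep strict ordering
  ps$recurrent_acvd_tp[] <- 0
  ps$utilities["GEN"] <- gen_utility
  ps
}

# Exhaustive net-monetary-benefit oracle for the efficiency frontier: a
# strategy is on the frontier iff it attains the maximum NMB at some
# willingness-to-pay. The NMB upper envelope only changes slope at pairwise
# crossing points, so evaluating at 0, every positive pairwise ICER, the
# midpoints between consecutive crossings, and one point beyond the largest
# crossing is exact.
nmb_frontier_oracle <- function(df) {
  n <- nrow(df)
  lam <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dq <- df$qaly[j] - df$qaly[i]
      if (dq != 0) {
        l <- (df$cost[j] - df$cost[i]) / dq
        if (is.finite(l) && l > 0) lam <- c(lam, l)
      }
    }
  }
  pts <- sort(unique(c(0, lam)))
  if (length(pts) > 1) {
    pts <- sort(c(pts, (pts[-1] + pts[-length(pts)]) / 2))
  }
  pts <- c(pts, max(pts) + 1)
  on_frontier <- rep(FALSE, n)
  for (l in pts) {
    nmb <- df$qaly * l - df$cost
    on_frontier[nmb >= max(nmb) - 1e-9] <- TRUE
  }
  sort(df$strategy[on_frontier])
}

random_strategies <- function(n, seed) {
  set.seed(seed)
  data.frame(strategy = paste0("S", seq_len(n)),
             cost = round(runif(n, 50, 500), 2),
             qaly = round(runif(n, 10, 20), 3),
             stringsAsFactors = FALSE)
}
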
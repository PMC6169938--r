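# Independent oracles, deliberately implemented by routes different from
# the package code they check.

# Absolute-risk oracle: midpoint-rule numerical integration of
# h1(t) rr exp(-int_0^t (h1 rr + h2)) over [age, age + horizon), on a fine
# grid aligned with the (integer) band edges. For piecewise-constant
# hazards the cumulative hazard computed by cumsum of midpoint values is
# exact, so the only error is the O(dt^2) midpoint quadrature error.
quadrature_abs_risk <- function(age, horizon, rr, hazards, dt = 1e-4) {
  t_mid <- seq(age + dt / 2, age + horizon - dt / 2, by = dt)
  band <- findInterval(t_mid, hazards$age_start)
  h1 <- hazards$incidence[band] * rr
  h2 <- hazards$competing_mortality[band]
  htot <- h1 + h2
  cumhaz <- cumsum(htot * dt) - htot * dt / 2  # hazard up to each midpoint
  sum(h1 * exp(-cumhaz) * dt)
}

# AUC oracle: explicit double loop over all case-control pairs.
brute_auc <- function(score, status) {
  x <- score[status == "case"]
  y <- score[status == "control"]
  tot <- 0
  for (xi in x) {
    for (yj in y) {
      tot <- tot + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  tot / (length(x) * length(y))
}

# Subject-by-subject NRI oracle from raw paired risks.
brute_nri <- function(clinical, combined, status, threshold) {
  hi_old <- clinical >= threshold
  hi_new <- combined >= threshold
  up <- !hi_old & hi_new
  down <- hi_old & !hi_new
  ca <- status == "case"
  mean(up[ca]) - mean(down[ca]) + mean(down[!ca]) - mean(up[!ca])
}

# HWE expectation of the adjusted risk value by direct enumeration of the
# three genotypes.
hwe_expected_adjusted <- function(p, or_) {
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  mu <- sum(w * or_^(0:2))
  sum(w * or_^(0:2) / mu)
}
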
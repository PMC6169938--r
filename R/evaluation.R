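# Case-control discrimination and calibration: OPERA, AUC (DeLong),
# paired AUC comparison, Hosmer-Lemeshow.

.check_status <- function(status) {
  status <- as.character(status)
  if (!all(status %in% c("case", "control"))) {
    stop("status must be coded case/control")
  }
  if (length(unique(status)) < 2L) {
    stop("both cases and controls are required")
  }
  status
}

#' Odds ratio per age-adjusted standard deviation (OPERA)
#'
#' Expresses a risk score's case-control association on a common scale:
#' OPERA = OR^s, the odds ratio per standard deviation of the score after
#' adjustment for the other fitted factors (here, age), with s estimated
#' from the controls. Implementation: (i) the log score is regressed
#' linearly on age among controls and s is the residual SD; (ii) a
#' logistic regression of status on the log score gives the coefficient
#' beta and its SE — with age as a covariate (`method = "covariate"`,
#' default) or after residualizing the score on age and fitting the
#' residual alone (`method = "residualize"`); (iii)
#' `OPERA = exp(beta * s)` with Wald 95% CI `exp((beta +/- 1.96 SE) * s)`.
#' OPERA is invariant to positive rescaling of the raw score.
#'
#' @param log_score per-subject natural-log risk score.
#' @param status case/control labels.
#' @param age per-subject age in years.
#' @param score_name label carried into the result.
#' @param method age-adjustment layout, see above.
#' @return A list of class `opera_estimate`: `score_name, opera_or,
#'   ci_low, ci_high, p_value, s, beta, se`.
#' @export
opera <- function(log_score, status, age,
                  score_name = deparse(substitute(log_score)),
                  method = c("covariate", "residualize")) {
  method <- match.arg(method)
  status <- .check_status(status)
  if (length(log_score) < 20L) stop("OPERA requires n >= 20")
  if (stats::var(log_score) == 0) stop("zero-variance score")
  y <- as.integer(status == "case")
  ctrl <- status == "control"

  if (method == "covariate") {
    s_fit <- stats::lm(log_score[ctrl] ~ age[ctrl])
    s <- summary(s_fit)$sigma
    fit <- stats::glm(y ~ log_score + age, family = stats::binomial())
    co <- summary(fit)$coefficients["log_score", ]
  } else {
    resid_all <- stats::residuals(stats::lm(log_score ~ age))
    s <- stats::sd(resid_all[ctrl])
    fit <- stats::glm(y ~ resid_all, family = stats::binomial())
    co <- summary(fit)$coefficients["resid_all", ]
  }
  beta <- co[["Estimate"]]
  se <- co[["Std. Error"]]
  if (!fit$converged || se > 50) {
    stop("logistic fit did not stabilize (possible perfect separation): ",
         "beta = ", signif(beta, 3), ", SE = ", signif(se, 3))
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(
    score_name = score_name,
    opera_or = exp(beta * s),
    ci_low = exp((beta - 1.96 * se) * s),
    ci_high = exp((beta + 1.96 * se) * s),
    p_value = p,
    s = s, beta = beta, se = se, method = method
  ), class = "opera_estimate")
}

#' @export
print.opera_estimate <- function(x, ...) {
  cat(sprintf("OPERA [%s]: %.3f (95%% CI %.3f, %.3f), P = %.3g (s = %.3f)\n",
              x$score_name, x$opera_or, x$ci_low, x$ci_high, x$p_value, x$s))
  invisible(x)
}

# DeLong structural components: per-case and per-control placement values.
.delong_components <- function(score, status) {
  x <- score[status == "case"]
  y <- score[status == "control"]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = length(x), n = length(y))
}

#' AUC with DeLong confidence interval
#'
#' Probability that a random case outscores a random control (ties count
#' one half), with the DeLong variance for the 95% CI.
#'
#' @param score per-subject risk score.
#' @param status case/control labels.
#' @param score_name label carried into the result.
#' @return A list of class `auc_estimate`: `score_name, auc, ci_low,
#'   ci_high, se`.
#' @export
auc_estimate <- function(score, status,
                         score_name = deparse(substitute(score))) {
  status <- .check_status(status)
  d <- .delong_components(score, status)
  v <- stats::var(d$v10) / d$m + stats::var(d$v01) / d$n
  se <- sqrt(v)
  structure(list(
    score_name = score_name, auc = d$auc,
    ci_low = max(0, d$auc - 1.96 * se),
    ci_high = min(1, d$auc + 1.96 * se),
    se = se
  ), class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC [%s]: %.3f (95%% CI %.3f, %.3f)\n",
              x$score_name, x$auc, x$ci_low, x$ci_high))
  invisible(x)
}

#' DeLong test comparing two correlated AUCs
#'
#' Paired comparison of two scores measured on the same subjects:
#' chi-square = (delta AUC)^2 / var(delta AUC) on 1 degree of freedom,
#' with the covariance of the placement values accounting for the pairing.
#' Identical scores give chi-square 0 and P = 1 exactly.
#'
#' @param score_a,score_b paired per-subject scores (same subjects, same
#'   order).
#' @param status case/control labels.
#' @return List with `auc_a, auc_b, delta, chisq, df, p_value`.
#' @export
auc_compare <- function(score_a, score_b, status) {
  status <- .check_status(status)
  if (length(score_a) != length(score_b) ||
      length(score_a) != length(status)) {
    stop("scores must be paired on the same subjects")
  }
  a <- .delong_components(score_a, status)
  b <- .delong_components(score_b, status)
  delta <- a$auc - b$auc
  v <- (stats::var(a$v10) + stats::var(b$v10) -
          2 * stats::cov(a$v10, b$v10)) / a$m +
       (stats::var(a$v01) + stats::var(b$v01) -
          2 * stats::cov(a$v01, b$v01)) / a$n
  if (delta == 0) {
    chisq <- 0
  } else if (v <= 0) {
    stop("degenerate variance in paired AUC comparison")
  } else {
    chisq <- delta^2 / v
  }
  list(auc_a = a$auc, auc_b = b$auc, delta = delta,
       chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into deciles of fitted risk (equal counts, ties kept
#' together), then
#' \eqn{\chi^2 = \sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g))} on
#' `n_groups - 2` degrees of freedom. Groups whose expected count is
#' degenerate (0 or equal to the group size) are merged with a neighbour
#' with a warning, reducing the degrees of freedom accordingly.
#'
#' @param prob fitted probabilities in `(0, 1)`.
#' @param status case/control labels.
#' @param n_groups number of risk groups (default 10).
#' @return List with `chisq, df, p_value, n_groups_used` and the per-group
#'   `table` (observed, expected, size).
#' @export
hosmer_lemeshow <- function(prob, status, n_groups = 10) {
  status <- .check_status(status)
  if (any(prob <= 0 | prob >= 1)) {
    stop("fitted probabilities must lie strictly in (0, 1)")
  }
  y <- as.integer(status == "case")
  breaks <- unique(stats::quantile(prob, probs = seq(0, 1,
                                                     length.out = n_groups + 1)))
  if (length(breaks) < 2L) {
    # all probabilities identical: a single degenerate group
    grp <- factor(rep(1L, length(prob)))
  } else {
    grp <- cut(prob, breaks = breaks, include.lowest = TRUE)
  }
  O <- tapply(y, grp, sum)
  E <- tapply(prob, grp, sum)
  n_g <- tapply(rep(1L, length(prob)), grp, sum)
  keep <- !is.na(n_g)
  O <- O[keep]; E <- E[keep]; n_g <- n_g[keep]

  # merge degenerate groups (expected 0 or n_g) into the previous one
  degen <- function(E, n_g) E == 0 | E == n_g
  while (length(n_g) > 1L && any(degen(E, n_g))) {
    i <- which(degen(E, n_g))[1]
    j <- if (i == 1L) 2L else i - 1L
    warning("merging degenerate Hosmer-Lemeshow group ", i,
            " with neighbour")
    O[j] <- O[j] + O[i]; E[j] <- E[j] + E[i]; n_g[j] <- n_g[j] + n_g[i]
    O <- O[-i]; E <- E[-i]; n_g <- n_g[-i]
  }
  g <- length(n_g)
  denom <- E * (1 - E / n_g)
  chisq <- sum((O - E)^2 / denom)
  df <- max(1L, g - 2L)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df = df, lower.tail = FALSE),
       n_groups_used = g,
       table = data.frame(observed = as.numeric(O),
                          expected = as.numeric(E),
                          size = as.numeric(n_g)))
}

#' ROC curve coordinates
#'
#' @param score per-subject risk score.
#' @param status case/control labels.
#' @return `data.frame` with `threshold, fpr, tpr`, one row per distinct
#'   score value plus the endpoints.
#' @export
roc_points <- function(score, status) {
  status <- .check_status(status)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  cases <- score[status == "case"]
  ctrls <- score[status == "control"]
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(ctrls >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(cases >= t), numeric(1))
  )
}

#' OPERA and AUC for every risk score in a score set
#'
#' One row per log-transformed score (5-year BCRAT, lifetime BCRAT, SNP,
#' and the two combined scores): OPERA with CI and P, and AUC with CI.
#'
#' @param scores a `risk_score_set` (log columns added if absent).
#' @param method OPERA age-adjustment layout, see [opera()].
#' @return `data.frame`, one row per score.
#' @export
evaluate_scores <- function(scores, method = c("covariate", "residualize")) {
  method <- match.arg(method)
  if (!"log_snp_score" %in% names(scores)) {
    scores <- log_transform_scores(scores)
  }
  rows <- lapply(SCORE_COLUMNS, function(col) {
    ls <- scores[[paste0("log_", col)]]
    op <- opera(ls, scores$status, scores$age, score_name = col,
                method = method)
    au <- auc_estimate(ls, scores$status, score_name = col)
    data.frame(score = col,
               opera_or = op$opera_or, opera_ci_low = op$ci_low,
               opera_ci_high = op$ci_high, opera_p = op$p_value,
               s = op$s,
               auc = au$auc, auc_ci_low = au$ci_low,
               auc_ci_high = au$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
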
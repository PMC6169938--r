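# Guideline-threshold risk categorization, reclassification tables and the
# two-category net reclassification improvement (NRI).
#
# Default thresholds follow clinical guidelines: 1.66% 5-year risk
# (chemoprevention discussion) and 20% lifetime risk (supplemental MRI
# screening); the boundary value itself is high risk.

#' Classify an absolute risk against a threshold
#'
#' @param risk absolute risk in `[0, 1]` (vectorized).
#' @param threshold cutoff; `risk >= threshold` is `high`.
#' @return Factor with levels `low, high`.
#' @export
classify_risk <- function(risk, threshold) {
  if (any(risk < 0 | risk > 1)) stop("risk must lie in [0, 1]")
  factor(ifelse(risk >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Construct a reclassification table from 2x2 counts
#'
#' Counts are indexed (clinical class -> combined class) over
#' `{low, high}`, separately for cases and controls.
#'
#' @param case_counts,control_counts 2x2 matrices (or length-4 vectors in
#'   row-major order low->low, low->high, high->low, high->high).
#' @param threshold the absolute-risk cutoff the table was built at (may
#'   be `NA` for tables re-entered from print).
#' @return A list of class `reclass_table`.
#' @export
reclass_table <- function(case_counts, control_counts, threshold = NA_real_) {
  shape <- function(x, what) {
    if (!is.matrix(x)) {
      if (length(x) != 4L) stop(what, " must be 2x2 (or length 4)")
      x <- matrix(as.numeric(x), 2, 2, byrow = TRUE)
    }
    if (any(x < 0) || any(x != round(x))) {
      stop(what, " must be non-negative integers")
    }
    dimnames(x) <- list(clinical = c("low", "high"),
                        combined = c("low", "high"))
    x
  }
  cc <- shape(case_counts, "case_counts")
  kk <- shape(control_counts, "control_counts")
  structure(list(threshold = threshold,
                 case_counts = cc, control_counts = kk,
                 n_cases = sum(cc), n_controls = sum(kk)),
            class = "reclass_table")
}

#' @export
print.reclass_table <- function(x, ...) {
  cat("Reclassification table",
      if (!is.na(x$threshold)) sprintf("(threshold %.4g)", x$threshold),
      "\nCases (n =", x$n_cases, "):\n")
  print(x$case_counts)
  cat("Controls (n =", x$n_controls, "):\n")
  print(x$control_counts)
  invisible(x)
}

#' Cross-tabulate clinical vs combined risk classifications
#'
#' @param clinical,combined paired per-subject absolute risks (same
#'   subjects, same order).
#' @param status case/control labels.
#' @param threshold absolute-risk cutoff applied to both scores.
#' @return A `reclass_table`.
#' @export
cross_tabulate <- function(clinical, combined, status, threshold) {
  if (length(clinical) != length(combined) ||
      length(clinical) != length(status)) {
    stop("clinical and combined risks must be paired per subject")
  }
  status <- .check_status(status)
  cl <- classify_risk(clinical, threshold)
  cb <- classify_risk(combined, threshold)
  tab <- function(keep) {
    t(vapply(c("low", "high"), function(a) {
      vapply(c("low", "high"), function(b) {
        sum(keep & cl == a & cb == b)
      }, numeric(1))
    }, numeric(2)))
  }
  reclass_table(tab(status == "case"), tab(status == "control"), threshold)
}

#' Net reclassification improvement with asymptotic CI
#'
#' `NRI = P(up|case) - P(down|case) + P(down|control) - P(up|control)`,
#' where up/down are moves across the threshold when the combined score
#' replaces the clinical one. The CI uses the standard asymptotic variance
#' for the two-category NRI,
#' `var = [(p_up,ca + p_dn,ca) - (p_up,ca - p_dn,ca)^2]/n_cases + (control
#' analog)`, with a 1.96 normal quantile.
#'
#' @param table a `reclass_table`.
#' @return A list of class `nri_result` with `nri`, `ci_low`, `ci_high`,
#'   `se`, and the four `components`.
#' @export
nri <- function(table) {
  if (table$n_cases == 0 || table$n_controls == 0) {
    stop("NRI requires at least one case and one control")
  }
  up_ca <- table$case_counts["low", "high"] / table$n_cases
  dn_ca <- table$case_counts["high", "low"] / table$n_cases
  up_co <- table$control_counts["low", "high"] / table$n_controls
  dn_co <- table$control_counts["high", "low"] / table$n_controls
  est <- up_ca - dn_ca + dn_co - up_co
  v <- ((up_ca + dn_ca) - (up_ca - dn_ca)^2) / table$n_cases +
       ((up_co + dn_co) - (up_co - dn_co)^2) / table$n_controls
  se <- sqrt(v)
  structure(list(
    nri = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    components = c(p_up_case = up_ca, p_down_case = dn_ca,
                   p_up_control = up_co, p_down_control = dn_co)
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI = %.3f (95%% CI %.3f, %.3f)\n",
              x$nri, x$ci_low, x$ci_high))
  invisible(x)
}

#' NRI directly from eight printed cell counts
#'
#' Re-analysis entry point: reproduces a published two-category NRI from
#' the printed reclassification table alone.
#'
#' @param case_counts,control_counts length-4 vectors in row-major order
#'   (low->low, low->high, high->low, high->high).
#' @param threshold optional cutoff recorded on the table.
#' @return An `nri_result`.
#' @export
nri_from_table <- function(case_counts, control_counts,
                           threshold = NA_real_) {
  nri(reclass_table(case_counts, control_counts, threshold))
}

#' Seeded bootstrap CI for the NRI
#'
#' Percentile CI from stratified resampling of cases and controls.
#'
#' @param clinical,combined paired per-subject absolute risks.
#' @param status case/control labels.
#' @param threshold absolute-risk cutoff.
#' @param n_boot number of resamples (default 2000).
#' @param seed RNG seed.
#' @return An `nri_result` whose CI is the bootstrap percentile interval
#'   (extra element `n_boot`).
#' @export
nri_bootstrap <- function(clinical, combined, status, threshold,
                          n_boot = 2000, seed = 1) {
  status <- .check_status(status)
  point <- nri(cross_tabulate(clinical, combined, status, threshold))
  ica <- which(status == "case")
  ico <- which(status == "control")
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(ica, replace = TRUE), sample(ico, replace = TRUE))
    nri(cross_tabulate(clinical[i], combined[i], status[i], threshold))$nri
  }, numeric(1))
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  out <- point
  out$ci_low <- ci[1]; out$ci_high <- ci[2]; out$n_boot <- n_boot
  out
}

#' Reclassified fractions under two denominators
#'
#' The share of subjects moved across the threshold, reported both among
#' the whole stratum and among the subjects on the relevant side of the
#' threshold beforehand (up-moves among the previously-low, down-moves
#' among the previously-high). An empty denominator yields `NA` with a
#' warning.
#'
#' @param table a `reclass_table`.
#' @return `data.frame` with columns `stratum, direction, denominator,
#'   numerator_n, denominator_n, fraction`.
#' @export
reclassified_fractions <- function(table) {
  one <- function(counts, total, stratum) {
    up <- counts["low", "high"]; dn <- counts["high", "low"]
    low_row <- sum(counts["low", ]); high_row <- sum(counts["high", ])
    frac <- function(num, den, what) {
      if (den == 0) {
        warning("empty denominator (", what, ", ", stratum,
                "): fraction undefined")
        return(NA_real_)
      }
      num / den
    }
    data.frame(
      stratum = stratum,
      direction = c("up", "up", "down", "down"),
      denominator = c("all", "previously_low", "all", "previously_high"),
      numerator_n = c(up, up, dn, dn),
      denominator_n = c(total, low_row, total, high_row),
      fraction = c(frac(up, total, "all"),
                   frac(up, low_row, "previously low"),
                   frac(dn, total, "all"),
                   frac(dn, high_row, "previously high")),
      stringsAsFactors = FALSE
    )
  }
  rbind(one(table$case_counts, table$n_cases, "case"),
        one(table$control_counts, table$n_controls, "control"))
}
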
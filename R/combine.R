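# Combined clinical x genetic risk score and its log transforms.

#' Combine a SNP score with an absolute risk
#'
#' Straight multiplication, capped at 1: the combined score is compared
#' against guideline thresholds as an absolute risk, so it must keep
#' probability semantics. With a population-mean SNP score of ~1 the cap
#' essentially never binds in realistic cohorts.
#'
#' @param snp_score positive SNP-based relative score (vectorized).
#' @param absolute_risk clinical absolute risk in `(0, 1]`.
#' @return `min(1, snp_score * absolute_risk)`.
#' @export
combine_risk <- function(snp_score, absolute_risk) {
  if (any(snp_score <= 0)) stop("snp_score must be positive")
  if (any(absolute_risk <= 0)) {
    stop("absolute risk must be positive (log transform downstream)")
  }
  if (any(absolute_risk > 1)) stop("absolute risk cannot exceed 1")
  pmin(1, snp_score * absolute_risk)
}

#' Assemble the per-subject risk score set
#'
#' Joins PRS results with the 5-year/lifetime clinical projections and the
#' questionnaire, and computes both combined scores.
#'
#' @param prs a `prs_result` from [compute_prs()].
#' @param gail output of [score_cohort()].
#' @param subjects a `questionnaire` data frame.
#' @return A `data.frame` of class `risk_score_set` with columns
#'   `subject_id, status, age, bcrat_5yr, bcrat_lifetime, snp_score,
#'   combined_5yr, combined_lifetime`.
#' @export
build_risk_scores <- function(prs, gail, subjects) {
  m <- merge(subjects[, c("subject_id", "status", "age")],
             prs[, c("subject_id", "snp_score")], by = "subject_id")
  m <- merge(m, gail[, c("subject_id", "five_year", "lifetime")],
             by = "subject_id")
  if (nrow(m) == 0L) stop("no subjects shared across PRS, Gail and questionnaire")
  out <- data.frame(
    subject_id = m$subject_id,
    status = m$status,
    age = m$age,
    bcrat_5yr = m$five_year,
    bcrat_lifetime = m$lifetime,
    snp_score = m$snp_score,
    combined_5yr = combine_risk(m$snp_score, m$five_year),
    combined_lifetime = combine_risk(m$snp_score, m$lifetime),
    stringsAsFactors = FALSE
  )
  class(out) <- c("risk_score_set", "data.frame")
  out
}

SCORE_COLUMNS <- c("bcrat_5yr", "bcrat_lifetime", "snp_score",
                   "combined_5yr", "combined_lifetime")

#' Natural-log transforms of the five risk scores
#'
#' All analyses run on log scores; every raw score must be strictly
#' positive. When the probability cap did not bind,
#' `log_combined = log_snp + log_bcrat` exactly.
#'
#' @param scores a `risk_score_set`.
#' @return The same data frame with `log_<score>` columns appended.
#' @export
log_transform_scores <- function(scores) {
  for (col in SCORE_COLUMNS) {
    bad <- scores[[col]] <= 0
    if (any(bad)) {
      stop("non-positive ", col, " for subject ",
           scores$subject_id[which(bad)[1]])
    }
    scores[[paste0("log_", col)]] <- log(scores[[col]])
  }
  scores
}

#' Pearson correlations among the log risk scores
#'
#' @param scores a `risk_score_set` with log columns (see
#'   [log_transform_scores()]); at least 3 subjects.
#' @return Symmetric correlation matrix over the five log scores with unit
#'   diagonal; pairs involving a zero-variance score are `NA` (with a
#'   warning).
#' @export
score_correlations <- function(scores) {
  if (nrow(scores) < 3L) stop("need at least 3 subjects for correlations")
  logs <- paste0("log_", SCORE_COLUMNS)
  miss <- setdiff(logs, names(scores))
  if (length(miss)) scores <- log_transform_scores(scores)
  m <- as.matrix(scores[, logs])
  vars <- apply(m, 2, stats::var)
  cc <- suppressWarnings(stats::cor(m))
  if (any(vars == 0)) {
    warning("zero-variance log score(s): ",
            paste(logs[vars == 0], collapse = ", "),
            "; correlations reported as NA")
    cc[vars == 0, ] <- NA
    cc[, vars == 0] <- NA
  }
  diag(cc) <- 1
  cc
}
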
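# Normalized multiplicative SNP risk score.
#
# Each SNP contributes OR^dosage / mu, where mu is the Hardy-Weinberg
# population-average risk; the per-subject score is the product over the
# panel, so the population mean of every factor (and hence approximately of
# the score) is 1 by construction.

#' Unscaled population-average risk of one SNP
#'
#' \eqn{\mu = (1-p)^2 + 2p(1-p)\,OR + p^2 OR^2}: the expected per-genotype
#' relative risk under Hardy-Weinberg genotype frequencies at risk-allele
#' frequency `p`.
#'
#' @param p risk-allele frequency in `[0, 1]` (vectorized).
#' @param or_ per-allele odds ratio, `> 0` (vectorized).
#' @return Numeric vector of \eqn{\mu} values.
#' @export
population_average_risk <- function(p, or_) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("risk-allele frequency must be in [0, 1]")
  }
  if (any(!is.finite(or_) | or_ <= 0)) {
    stop("per-allele OR must be positive")
  }
  (1 - p)^2 + 2 * p * (1 - p) * or_ + p^2 * or_^2
}

#' Adjusted (population-normalized) risk value of one genotype
#'
#' `OR^dosage / mu`, the per-genotype relative risk rescaled so its
#' Hardy-Weinberg expectation is exactly 1.
#'
#' @param dosage risk-allele count in `{0, 1, 2}` (vectorized).
#' @param or_ per-allele odds ratio.
#' @param mu population-average risk from [population_average_risk()].
#' @return Numeric vector of adjusted risk values.
#' @export
adjusted_risk_value <- function(dosage, or_, mu) {
  if (any(!dosage %in% c(0, 1, 2))) {
    stop("dosage must be 0, 1 or 2")
  }
  or_^dosage / mu
}

#' Per-subject SNP-based risk score
#'
#' Multiplies the adjusted risk values over all non-missing panel SNPs
#' (accumulated in log space). A missing genotype contributes the neutral
#' factor 1 — the expectation of its adjusted risk value under HWE — and is
#' counted in `n_missing`; a subject missing every genotype therefore
#' scores exactly 1.
#'
#' @param genotypes integer dosage matrix (subjects x SNPs, `NA` missing),
#'   columns matching the panel rsIDs (reordered if needed).
#' @param panel an `snp_panel`.
#' @return A `data.frame` of class `prs_result` with columns
#'   `subject_id, snp_score, n_missing`.
#' @export
compute_prs <- function(genotypes, panel) {
  if (nrow(panel) == 0L) stop("empty SNP panel")
  if (!setequal(colnames(genotypes), panel$rsid)) {
    stop("genotype matrix columns do not match panel rsids")
  }
  genotypes <- genotypes[, panel$rsid, drop = FALSE]
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) stop("dosage outside {0,1,2} in genotype matrix")

  log_or <- log(panel$or)
  log_mu <- log(panel$mu)
  # per-SNP log contribution d*log(OR) - log(mu); missing -> 0
  contrib <- sweep(sweep(genotypes, 2, log_or, `*`), 2, log_mu, `-`)
  n_missing <- rowSums(is.na(genotypes))
  contrib[is.na(contrib)] <- 0
  out <- data.frame(
    subject_id = rownames(genotypes),
    snp_score = exp(rowSums(contrib)),
    n_missing = as.integer(n_missing),
    stringsAsFactors = FALSE
  )
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Case/control summary of SNP scores
#'
#' Mean and SD of the SNP score per status stratum plus overall, for
#' reporting alongside the published case/control score distributions.
#'
#' @param results a `prs_result` from [compute_prs()].
#' @param subjects a `questionnaire` data frame with `status`.
#' @return `data.frame` with columns `stratum, n, mean, sd`.
#' @export
prs_summary <- function(results, subjects) {
  m <- merge(results, subjects[, c("subject_id", "status")],
             by = "subject_id")
  if (nrow(m) == 0L) stop("no overlap between PRS results and subjects")
  one <- function(x, label) {
    s <- if (length(x) < 2L) {
      warning("SD undefined for stratum '", label,
              "' with ", length(x), " subject(s); reporting 0")
      0
    } else {
      stats::sd(x)
    }
    data.frame(stratum = label, n = length(x),
               mean = mean(x), sd = s, stringsAsFactors = FALSE)
  }
  rbind(
    one(m$snp_score[m$status == "case"], "case"),
    one(m$snp_score[m$status == "control"], "control"),
    one(m$snp_score, "overall")
  )
}
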
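# Synthetic case-control cohort generator with known ground truth.
#
# Emulates the structure of the study data the pipeline expects: a 75-SNP
# panel, HWE genotypes, a BCRAT-style questionnaire with realistic
# missingness (near-total for biopsies/hyperplasia, ~25% for family
# history), a smooth hazard table, and logistic case assignment driven by
# the true log clinical and log SNP scores, with age-band-matched controls.

#' Simulation configuration
#'
#' Defaults state the emulated world: a 75-SNP panel with per-allele
#' log-ORs ~ N(0, 0.08) (chosen so the SNP-score dispersion matches the
#' reported case/control SDs of ~0.4), frequencies uniform on
#' `[0.05, 0.95]`, 319 cases and 559 controls, unit multipliers on both
#' true log scores, and Table-1-like questionnaire missingness.
#'
#' @param n_snps panel size (default 75).
#' @param freq_range risk-allele frequency range (uniform draw).
#' @param log_or_mean,log_or_sd normal distribution of per-allele log-ORs.
#' @param n_cases,n_controls cohort sizes (defaults 319 / 559).
#' @param genetic_effect multiplier on the true log SNP score in the
#'   case-assignment model.
#' @param clinical_effect multiplier on the true log 5-year clinical risk.
#' @param genotype_missing per-genotype missing probability.
#' @param quest_missing named per-field missing probabilities for the five
#'   questionnaire variables.
#' @param nulliparous_prob probability of no live birth among parity-known
#'   subjects.
#' @param family_history_oversampling enrich case sampling for family
#'   history (a study-design artifact of the emulated cohort).
#' @param fh_enrichment sampling-weight multiplier per affected
#'   first-degree relative category when oversampling is on.
#' @param pool_factor source-population size as a multiple of
#'   `n_cases + n_controls`.
#' @param case_margin expected-case multiplier used when solving the
#'   model intercept, so the realized case count exceeds `n_cases` with
#'   high probability.
#' @param seed integer seed; fully determines all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 75,
                       freq_range = c(0.05, 0.95),
                       log_or_mean = 0, log_or_sd = 0.08,
                       n_cases = 319, n_controls = 559,
                       genetic_effect = 1, clinical_effect = 1,
                       genotype_missing = 0.02,
                       quest_missing = c(n_first_degree_relatives = 0.25,
                                         age_menarche = 0.03,
                                         age_first_birth = 0.15,
                                         n_biopsies = 0.94,
                                         hyperplasia = 0.93),
                       nulliparous_prob = 0.08,
                       family_history_oversampling = FALSE,
                       fh_enrichment = 3,
                       pool_factor = 4, case_margin = 1.3,
                       seed = 1) {
  if (n_snps < 1 || n_cases < 1 || n_controls < 1) {
    stop("counts must be positive")
  }
  if (length(freq_range) != 2 || freq_range[1] > freq_range[2] ||
      freq_range[1] < 0 || freq_range[2] > 1) {
    stop("degenerate freq_range: need 0 <= lo <= hi <= 1")
  }
  probs <- c(genotype_missing, quest_missing, nulliparous_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (pool_factor * case_margin <= 1) stop("pool too small for case target")
  structure(as.list(environment()), class = "sim_config")
}

# Derive k stage seeds from the master seed (kept below 2^31).
.derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Simulate a SNP panel
#'
#' @param config a `sim_config`.
#' @param seed stage seed (defaults to the config seed).
#' @return An `snp_panel` with `config$n_snps` rows.
#' @export
simulate_panel <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_snps
  snp_panel(
    rsid = sprintf("rs%05d", seq_len(n)),
    risk_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    or = exp(stats::rnorm(n, config$log_or_mean, config$log_or_sd)),
    freq = stats::runif(n, config$freq_range[1], config$freq_range[2])
  )
}

#' Simulate HWE genotypes for a panel
#'
#' Dosages are drawn Binomial(2, p) independently per SNP (Hardy-Weinberg,
#' no linkage disequilibrium, matching the score's independence
#' assumption).
#'
#' @param panel an `snp_panel`.
#' @param n_subjects number of subjects.
#' @param seed RNG seed.
#' @param missing_rate per-genotype missing probability.
#' @param id_prefix subject id prefix.
#' @return Integer dosage matrix with subject ids as rownames.
#' @export
simulate_genotypes <- function(panel, n_subjects, seed = 1,
                               missing_rate = 0, id_prefix = "S") {
  set.seed(seed)
  m <- vapply(panel$freq,
              function(p) stats::rbinom(n_subjects, 2L, p),
              integer(n_subjects))
  if (n_subjects == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(sprintf("%s%05d", id_prefix, seq_len(n_subjects)),
                      panel$rsid)
  if (missing_rate > 0) {
    m[stats::runif(length(m)) < missing_rate] <- NA_integer_
  }
  m
}

# Control-like marginal distributions for the questionnaire fields
# (5-year age bands 35-85; menarche 9-17; first birth bands; biopsies;
# hyperplasia), loosely following a population-based control sample.
.age_band_weights <- c(7, 12.3, 15.7, 22.7, 18.1, 9.5, 8.2, 3.8, 2.7, 1)
.menarche_weights <- c(25, 53, 55, 166, 118, 55, 32, 26, 15)  # ages 9..17
.afb_band_weights <- c(181, 182, 66, 37, 8)  # <=19,20-24,25-29,30-34,>=35

#' Simulate questionnaire records (status unset)
#'
#' Ages are drawn over 35-85 from 5-year bands with population-like
#' weights; the five risk-factor fields from control-like marginals; then
#' per-field missingness is applied (heavy for biopsies and hyperplasia,
#' moderate for family history, emulating real questionnaire data).
#'
#' @param n_subjects number of records.
#' @param config a `sim_config` (missingness and nulliparous settings).
#' @param seed RNG seed.
#' @param id_prefix subject id prefix.
#' @return A `questionnaire` data frame with `status = NA`.
#' @export
simulate_questionnaire <- function(n_subjects, config = sim_config(),
                                   seed = config$seed, id_prefix = "S") {
  set.seed(seed)
  band <- sample.int(10L, n_subjects, replace = TRUE,
                     prob = .age_band_weights)
  age <- 35L + (band - 1L) * 5L + sample.int(5L, n_subjects,
                                             replace = TRUE) - 1L
  fdr <- sample(c("0", "1", "2+"), n_subjects, replace = TRUE,
                prob = c(0.85, 0.135, 0.015))
  menarche <- sample(9:17, n_subjects, replace = TRUE,
                     prob = .menarche_weights)
  nullip <- stats::runif(n_subjects) < config$nulliparous_prob
  afb_band <- sample.int(5L, n_subjects, replace = TRUE,
                         prob = .afb_band_weights)
  afb_lo <- c(16L, 20L, 25L, 30L, 35L)[afb_band]
  afb_hi <- c(19L, 24L, 29L, 34L, 40L)[afb_band]
  afb <- afb_lo + floor(stats::runif(n_subjects) * (afb_hi - afb_lo + 1L))
  afb[nullip] <- NA_integer_
  biopsies <- sample(0:2, n_subjects, replace = TRUE,
                     prob = c(0.775, 0.175, 0.05))
  hyp <- sample(c("no", "yes"), n_subjects, replace = TRUE,
                prob = c(0.9, 0.1))

  qm <- config$quest_missing
  drop <- function(p) stats::runif(n_subjects) < p
  fdr[drop(qm[["n_first_degree_relatives"]])] <- NA_character_
  menarche[drop(qm[["age_menarche"]])] <- NA_integer_
  afb_missing <- drop(qm[["age_first_birth"]])
  afb[afb_missing] <- NA_integer_
  nullip_out <- ifelse(afb_missing, NA, nullip)
  biopsies[drop(qm[["n_biopsies"]])] <- NA_integer_
  hyp[drop(qm[["hyperplasia"]])] <- NA_character_

  questionnaire_frame(
    subject_id = sprintf("%s%05d", id_prefix, seq_len(n_subjects)),
    status = rep(NA_character_, n_subjects),
    age = age,
    n_first_degree_relatives = fdr,
    age_menarche = menarche,
    age_first_birth = afb,
    nulliparous = nullip_out,
    n_biopsies = biopsies,
    hyperplasia = hyp
  )
}

#' Plausible default relative-risk model for simulations
#'
#' Gail-style log relative risks: family history is the strongest factor,
#' early menarche, later first birth, biopsies and hyperplasia contribute
#' moderately. Reference categories and UNKNOWN carry log-RR 0.
#'
#' @return An `rr_model`.
#' @export
default_rr_model <- function() {
  rr_model(list(
    n_first_degree_relatives = c("0" = 0, "1" = 0.45, "2+" = 0.9),
    age_menarche = c(">=14" = 0, "12-13" = 0.1, "<12" = 0.21),
    age_first_birth = c("<20" = 0, "20-24" = 0.12, "25-29" = 0.21,
                        ">=30" = 0.29, "nulliparous" = 0.29),
    n_biopsies = c("0" = 0, "1" = 0.46, "2+" = 0.62),
    hyperplasia = c("no" = 0, "yes" = 0.93)
  ))
}

#' Simulate a smooth hazard table
#'
#' Eleven 5-year bands over `[35, 90)`: incidence rising from ~1e-3 to
#' ~4.5e-3 per year (breast-cancer-like order of magnitude) and competing
#' mortality rising roughly exponentially from ~2e-3 to ~3e-2, each with a
#' small seeded log-normal jitter (incidence kept monotone).
#'
#' @param seed RNG seed.
#' @return A `hazard_table`.
#' @export
simulate_hazard_tables <- function(seed = 1) {
  set.seed(seed)
  starts <- seq(35, 85, by = 5)
  mids <- starts + 2.5
  h1 <- (1e-3 + 3.5e-3 * (mids - 37.5) / 50) * exp(stats::rnorm(11, 0, 0.05))
  h1 <- cummax(h1)
  h2 <- 2e-3 * exp(0.052 * (mids - 37.5)) * exp(stats::rnorm(11, 0, 0.05))
  hazard_table(starts, starts + 5, h1, h2)
}

#' Assign case/control status by a logistic model on the true log scores
#'
#' The case probability for pool member i is
#' `logit P_i = alpha + clinical_effect * log(bcrat_5yr_i) +
#' genetic_effect * log(snp_score_i)`, with `alpha` solved numerically so
#' the expected case count is `n_cases * case_margin` (the margin keeps
#' drawing `n_cases` actual cases feasible). Cases are sampled from the
#' realized cases (weighted by family history when oversampling is on);
#' the first `n_cases` controls are age-band-matched 1:1 to the sampled
#' cases and the remainder drawn at random, emulating a matched design
#' with a supplementary control series.
#'
#' @param subjects pool `questionnaire` (status unset).
#' @param prs pool `prs_result` (true, complete-genotype scores).
#' @param gail pool output of [score_cohort()].
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return List: `subjects` (the selected cohort with status filled,
#'   cases first), `truth` (alpha, effects, per-subject true scores and
#'   case probabilities for the pool).
#' @export
assign_status <- function(subjects, prs, gail, config, seed = config$seed) {
  set.seed(seed)
  stopifnot(identical(subjects$subject_id, prs$subject_id),
            identical(subjects$subject_id, gail$subject_id))
  n_pool <- nrow(subjects)
  eta <- config$clinical_effect * log(gail$five_year) +
    config$genetic_effect * log(prs$snp_score)
  target <- config$n_cases * config$case_margin
  if (target >= n_pool) stop("infeasible case count: pool too small")
  alpha <- stats::uniroot(
    function(a) sum(stats::plogis(a + eta)) - target,
    lower = -40, upper = 40, tol = 1e-10
  )$root
  p_case <- stats::plogis(alpha + eta)
  is_case <- stats::runif(n_pool) < p_case

  if (sum(is_case) < config$n_cases) {
    stop("infeasible case count: only ", sum(is_case),
         " realized cases for a target of ", config$n_cases,
         "; increase pool_factor or case_margin")
  }
  case_idx <- which(is_case)
  if (config$family_history_oversampling) {
    fdr <- as.character(subjects$n_first_degree_relatives[case_idx])
    w <- ifelse(is.na(fdr), 1,
                ifelse(fdr == "2+", config$fh_enrichment^2,
                       ifelse(fdr == "1", config$fh_enrichment, 1)))
    cases <- sample(case_idx, config$n_cases, prob = w)
  } else {
    cases <- sample(case_idx, config$n_cases)
  }

  # age-band matching: one control per case from the same 5-year band,
  # falling back to the nearest band with stock left
  band <- (subjects$age - 35L) %/% 5L
  avail <- setdiff(which(!is_case), integer(0))
  pool_by_band <- split(sample(avail), band[avail])
  matched <- integer(0)
  for (ci in cases) {
    b <- band[ci]
    bands_sorted <- names(pool_by_band)[
      order(abs(as.integer(names(pool_by_band)) - b))]
    picked <- NA_integer_
    for (bb in bands_sorted) {
      if (length(pool_by_band[[bb]]) > 0L) {
        picked <- pool_by_band[[bb]][1L]
        pool_by_band[[bb]] <- pool_by_band[[bb]][-1L]
        break
      }
    }
    if (is.na(picked)) stop("infeasible control matching: pool exhausted")
    matched <- c(matched, picked)
  }
  remaining <- setdiff(avail, matched)
  n_extra <- config$n_controls - config$n_cases
  if (n_extra < 0) stop("n_controls must be >= n_cases for matched design")
  if (length(remaining) < n_extra) {
    stop("infeasible control count: pool too small")
  }
  extra <- sample(remaining, n_extra)
  controls <- c(matched, extra)

  sel <- subjects[c(cases, controls), , drop = FALSE]
  sel$status <- factor(rep(c("case", "control"),
                           c(length(cases), length(controls))),
                       levels = c("control", "case"))
  rownames(sel) <- NULL
  list(
    subjects = sel,
    truth = list(alpha = alpha,
                 genetic_effect = config$genetic_effect,
                 clinical_effect = config$clinical_effect,
                 case_margin = config$case_margin,
                 pool_ids = subjects$subject_id,
                 pool_p_case = p_case,
                 pool_log_prs = log(prs$snp_score),
                 pool_log_bcrat_5yr = log(gail$five_year))
  )
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generative chain: panel, source-population questionnaire
#' and complete genotypes, hazard table, true clinical and SNP scores,
#' logistic case assignment with age-matched controls, then genotype
#' missingness on the delivered matrix. Fully deterministic under
#' `config$seed`.
#'
#' @param config a `sim_config`.
#' @return A `cohort_dataset` whose `truth` element carries the generator
#'   ground truth (effects, alpha, per-SNP log-ORs, seed).
#' @export
simulate_cohort <- function(config = sim_config()) {
  seeds <- .derive_seeds(config$seed, 6L)
  panel <- simulate_panel(config, seeds[1])
  n_pool <- ceiling(config$pool_factor *
                      (config$n_cases + config$n_controls))
  quest <- simulate_questionnaire(n_pool, config, seeds[2])
  geno <- simulate_genotypes(panel, n_pool, seeds[3], missing_rate = 0)
  hazards <- simulate_hazard_tables(seeds[4])
  model <- default_rr_model()
  gail <- score_cohort(quest, model, hazards)
  prs <- compute_prs(geno, panel)
  sel <- assign_status(quest, prs, gail, config, seeds[5])

  g <- geno[sel$subjects$subject_id, , drop = FALSE]
  if (config$genotype_missing > 0) {
    set.seed(seeds[6])
    g[stats::runif(length(g)) < config$genotype_missing] <- NA_integer_
  }
  truth <- sel$truth
  truth$seed <- config$seed
  truth$log_or <- stats::setNames(log(panel$or), panel$rsid)
  cohort_dataset(sel$subjects, g, panel,
                 hazards = hazards, rr_model = model, truth = truth)
}

#' Write a synthetic cohort's input files to a directory
#'
#' Emits the four pipeline inputs (`panel.csv`, `genotypes.csv`,
#' `questionnaire.csv`, `risk_config.json`) plus `truth.json` with the
#' generator ground truth, so external harnesses can test recovery.
#'
#' @param cohort a `cohort_dataset` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    panel = file.path(dir, "panel.csv"),
    genotypes = file.path(dir, "genotypes.csv"),
    questionnaire = file.path(dir, "questionnaire.csv"),
    config = file.path(dir, "risk_config.json"),
    truth = file.path(dir, "truth.json")
  )
  write_snp_panel(cohort$panel, paths["panel"])
  write_genotype_matrix(cohort$genotypes, paths["genotypes"])
  write_questionnaire(cohort$subjects, paths["questionnaire"])
  write_risk_config(cohort$hazards, cohort$rr_model, paths["config"])
  truth <- cohort$truth
  truth$pool_ids <- NULL  # keep the file small
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  paths
}
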
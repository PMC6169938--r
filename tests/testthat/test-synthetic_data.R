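# Generator: determinism, marginal behaviour, case-assignment structure.

test_that("sim_config validates its stated world", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_snps = 0), "positive")
  expect_error(sim_config(freq_range = c(0.9, 0.1)), "degenerate")
  expect_error(sim_config(genotype_missing = 1.5), "probabilities")
})

test_that("simulate_panel is seeded and honours the null config", {
  p1 <- simulate_panel(sim_config(seed = 31))
  p2 <- simulate_panel(sim_config(seed = 31))
  expect_identical(p1, p2)
  expect_identical(nrow(p1), 75L)

  null <- simulate_panel(sim_config(log_or_mean = 0, log_or_sd = 0,
                                    seed = 1))
  expect_equal(null$or, rep(1, 75))
  expect_equal(null$mu, rep(1, 75))
})

test_that("simulate_genotypes draws HWE dosages with requested missingness", {
  fixed <- snp_panel(c("z0", "zh"), c("A", "C"), c(1.2, 1.2), c(0, 0.5))
  g <- simulate_genotypes(fixed, 10000, seed = 7)
  expect_true(all(g[, "z0"] == 0L))
  # p = 0.5: genotype fractions near (.25, .5, .25); 3 SE of a proportion
  fr <- tabulate(g[, "zh"] + 1L, nbins = 3) / 10000
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
  expect_true(all(abs(fr - c(.25, .5, .25)) < 3 * se))
  # HWE chi-square is unremarkable
  expected <- c(.25, .5, .25) * 10000
  chi <- sum((tabulate(g[, "zh"] + 1L, nbins = 3) - expected)^2 / expected)
  expect_gt(pchisq(chi, df = 2, lower.tail = FALSE), 0.001)

  gm <- simulate_genotypes(fixed, 10000, seed = 8, missing_rate = 0.1)
  fmiss <- mean(is.na(gm))
  expect_lt(abs(fmiss - 0.1), 3 * sqrt(0.1 * 0.9 / length(gm)))
})

test_that("simulate_questionnaire applies per-field missingness", {
  cfg <- sim_config(quest_missing = c(n_first_degree_relatives = 0,
                                      age_menarche = 0,
                                      age_first_birth = 0,
                                      n_biopsies = 1,
                                      hyperplasia = 0),
                    nulliparous_prob = 0)
  q <- simulate_questionnaire(500, cfg, seed = 3)
  expect_true(all(is.na(q$n_biopsies)))              # near-total, like real data
  expect_true(!anyNA(q$age_menarche))
  expect_true(!anyNA(q$n_first_degree_relatives))
  expect_true(all(q$age >= 35 & q$age <= 85))

  q1 <- simulate_questionnaire(200, sim_config(seed = 4), seed = 9)
  q2 <- simulate_questionnaire(200, sim_config(seed = 4), seed = 9)
  expect_identical(q1, q2)
})

test_that("simulate_hazard_tables yields plausible, seeded tables", {
  h1 <- simulate_hazard_tables(seed = 5)
  h2 <- simulate_hazard_tables(seed = 5)
  expect_identical(h1, h2)
  expect_s3_class(h1, "hazard_table")
  expect_true(all(diff(h1$incidence) >= 0))
  expect_true(all(h1$incidence > 1e-4 & h1$incidence < 1e-2))

  # implied mean 5-year risks for a mid-life population fall in 0.5-3%
  risks <- absolute_risk(seq(40, 70, by = 5), 5, 1, h1)
  expect_true(mean(risks) > 0.005 && mean(risks) < 0.03)
})

test_that("assign_status shapes the cohort by the stated logistic model", {
  # positive genetic effect: case PRS mean exceeds control PRS mean
  co <- simulate_cohort(sim_config(seed = 37))
  prs <- compute_prs(co$genotypes, co$panel)
  ps <- prs_summary(prs, co$subjects)
  expect_gt(ps$mean[ps$stratum == "case"], ps$mean[ps$stratum == "control"])
  expect_identical(sum(co$subjects$status == "case"), 319L)
  expect_identical(sum(co$subjects$status == "control"), 559L)

  # zero genetic effect: PRS indistinguishable between strata
  co0 <- simulate_cohort(sim_config(seed = 41, genetic_effect = 0))
  prs0 <- compute_prs(co0$genotypes, co0$panel)
  m <- merge(prs0, co0$subjects[, c("subject_id", "status")])
  ks <- suppressWarnings(ks.test(m$snp_score[m$status == "case"],
                                 m$snp_score[m$status == "control"]))
  expect_gt(ks$p.value, 0.01)

  # age matching: case/control age-band distributions agree
  band <- function(a) cut(a, seq(35, 90, by = 5), right = FALSE)
  tb <- table(band(co$subjects$age), co$subjects$status)
  keep <- rowSums(tb) > 0
  chi <- suppressWarnings(chisq.test(tb[keep, ]))
  expect_gt(chi$p.value, 0.001)

  # infeasibility is a clean error
  expect_error(
    simulate_cohort(sim_config(seed = 1, n_cases = 400, n_controls = 500,
                               pool_factor = 1.01, case_margin = 1.3)),
    "pool|infeasible")
})

test_that("family-history oversampling enriches case family history", {
  cfg <- sim_config(seed = 43, family_history_oversampling = TRUE,
                    fh_enrichment = 4)
  co <- simulate_cohort(cfg)
  fdr <- co$subjects$n_first_degree_relatives
  fh_case <- mean(fdr[co$subjects$status == "case"] != "0", na.rm = TRUE)
  fh_ctrl <- mean(fdr[co$subjects$status == "control"] != "0",
                  na.rm = TRUE)
  expect_gt(fh_case, fh_ctrl * 1.5)
})

test_that("a seed fully determines the written cohort byte-for-byte", {
  cfg <- sim_config(seed = 47, n_cases = 50, n_controls = 90, n_snps = 10)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_cohort(simulate_cohort(cfg), d1)
  p2 <- write_cohort(simulate_cohort(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  # and a different seed changes the data
  d3 <- tempfile()
  p3 <- write_cohort(simulate_cohort(sim_config(seed = 48, n_cases = 50,
                                                n_controls = 90,
                                                n_snps = 10)), d3)
  expect_false(identical(readLines(p1[["genotypes"]]),
                         readLines(p3[["genotypes"]])))
})

test_that("truth payload records the generative parameters", {
  cfg <- sim_config(seed = 53, n_cases = 40, n_controls = 70, n_snps = 6,
                    genetic_effect = 0.8, clinical_effect = 1.2)
  co <- simulate_cohort(cfg)
  expect_equal(co$truth$genetic_effect, 0.8)
  expect_equal(co$truth$clinical_effect, 1.2)
  expect_identical(names(co$truth$log_or), co$panel$rsid)
  expect_equal(co$truth$log_or, log(co$panel$or), ignore_attr = TRUE)
  # alpha reproduces the expected-case calibration on the pool
  expected <- sum(plogis(co$truth$alpha +
                           cfg$clinical_effect * co$truth$pool_log_bcrat_5yr +
                           cfg$genetic_effect * co$truth$pool_log_prs))
  expect_equal(expected, cfg$n_cases * cfg$case_margin, tolerance = 1e-6)
})
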
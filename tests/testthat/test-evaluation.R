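# OPERA, AUC/DeLong, paired comparison, Hosmer-Lemeshow.

sim_logistic <- function(n, beta, seed) {
  set.seed(seed)
  x <- rnorm(n)
  age <- sample(35:85, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-0.5 + beta * x))
  list(x = x, age = age,
       status = ifelse(y == 1, "case", "control"))
}

test_that("opera recovers a known per-SD effect and is scale invariant", {
  d <- sim_logistic(2000, beta = 0.8, seed = 1)
  est <- opera(d$x, d$status, d$age, score_name = "x")
  # x ~ N(0,1) and age-independent, so s ~ 1 and OPERA ~ exp(0.8)
  expect_gt(est$ci_high, exp(0.8) * 0.95)
  expect_lt(est$ci_low, exp(0.8) * 1.05)
  expect_lt(est$p_value, 1e-6)
  expect_true(est$ci_low <= est$opera_or && est$opera_or <= est$ci_high)
  expect_equal(est$opera_or, exp(est$beta * est$s))

  # multiplying the *raw* score by a constant shifts the log score only
  shifted <- opera(d$x + log(3.7), d$status, d$age, score_name = "x")
  expect_equal(shifted$opera_or, est$opera_or, tolerance = 1e-10)
  expect_equal(shifted$s, est$s, tolerance = 1e-10)

  # residualize variant agrees closely when age is independent of score
  alt <- opera(d$x, d$status, d$age, method = "residualize")
  expect_equal(alt$opera_or, est$opera_or, tolerance = 0.05)
})

test_that("opera CI coverage is near nominal (recovery simulation)", {
  beta <- 0.5
  hits <- vapply(1:150, function(i) {
    d <- sim_logistic(400, beta = beta, seed = 1000 + i)
    e <- opera(d$x, d$status, d$age, score_name = "x")
    # target on the beta scale: CI for beta is (log ci)/s
    lo <- log(e$ci_low) / e$s; hi <- log(e$ci_high) / e$s
    lo <= beta && beta <= hi
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("opera is null-behaved and rejects degenerate input", {
  ps <- vapply(1:60, function(i) {
    d <- sim_logistic(300, beta = 0, seed = 2000 + i)
    opera(d$x, d$status, d$age, score_name = "x")$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)           # ~95% expected under the null
  expect_gt(suppressWarnings(ks.test(ps, punif)$p.value), 0.01)

  d <- sim_logistic(100, 0, seed = 3)
  expect_error(opera(rep(1, 100), d$status, d$age), "zero-variance")
  expect_error(opera(d$x[1:10], d$status[1:10], d$age[1:10]), "n >= 20")
  sep <- c(rnorm(50, -10), rnorm(50, 10))
  st <- rep(c("control", "case"), each = 50)
  expect_error(suppressWarnings(opera(sep, st, d$age)), "separation")
})

test_that("auc_estimate matches hand enumeration and brute force", {
  st <- c("case", "case", "control", "control")
  expect_equal(auc_estimate(c(3, 2, 1, 2), st)$auc, 0.875)  # 3.5/4 pairs
  expect_equal(auc_estimate(c(9, 8, 1, 2), st)$auc, 1.0)

  # antisymmetry
  set.seed(5)
  x <- rnorm(40); s <- sample(c("case", "control"), 40, replace = TRUE,
                              prob = c(.4, .6))
  expect_equal(auc_estimate(x, s)$auc + auc_estimate(-x, s)$auc, 1)

  # brute-force equivalence with ties present
  for (i in 1:20) {
    set.seed(100 + i)
    n <- sample(10:50, 1)
    s <- c("case", "control",
           sample(c("case", "control"), n - 2, replace = TRUE))
    x <- sample(1:8, n, replace = TRUE)  # heavy ties
    expect_equal(auc_estimate(x, s)$auc, brute_auc(x, s))
  }
  expect_error(auc_estimate(1:5, rep("case", 5)), "both")
})

test_that("auc_compare is exact at identity and powered when told apart", {
  set.seed(11)
  n <- 600
  truth <- rnorm(n)
  status <- ifelse(rbinom(n, 1, plogis(1.5 * truth)) == 1, "case",
                   "control")
  idt <- auc_compare(truth, truth, status)
  expect_equal(idt$chisq, 0)
  expect_equal(idt$p_value, 1)

  # true risk vs badly noised risk: delta > 0 and p small
  noisy <- truth + rnorm(n, 0, 3)
  cmp <- auc_compare(truth, noisy, status)
  expect_gt(cmp$delta, 0)
  expect_lt(cmp$p_value, 0.01)

  # adding independent noise to a *copy* is a null comparison
  ps <- vapply(1:40, function(i) {
    set.seed(300 + i)
    a <- rnorm(400)
    st <- ifelse(rbinom(400, 1, plogis(a)) == 1, "case", "control")
    b <- a + rnorm(400, 0, 0.05)
    auc_compare(a, b, st)$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.75)

  expect_error(auc_compare(truth, truth[-1], status), "paired")
})

test_that("hosmer_lemeshow calibration behaviour", {
  gen <- function(seed, n = 1000, distort = identity) {
    set.seed(seed)
    p <- plogis(rnorm(n, -1, 1))
    y <- rbinom(n, 1, p)
    list(p = distort(p), status = ifelse(y == 1, "case", "control"))
  }
  # well calibrated: p-values roughly uniform over replicates
  ps <- vapply(1:60, function(i) {
    d <- gen(400 + i)
    hosmer_lemeshow(d$p, d$status)$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(suppressWarnings(ks.test(ps, punif)$p.value), 0.01)

  # gross miscalibration (squared probabilities) detected at n = 2000
  rejections <- vapply(1:10, function(i) {
    d <- gen(900 + i, n = 2000, distort = function(p) p^2)
    hosmer_lemeshow(d$p, d$status)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)

  # all probabilities equal to the case fraction: chisq ~ 0
  set.seed(77)
  st <- sample(c("case", "control"), 200, replace = TRUE)
  pbar <- mean(st == "case")
  res <- hosmer_lemeshow(rep(pbar, 200), st)
  expect_lt(res$chisq, 1e-10)
  expect_identical(res$n_groups_used, 1L)

  expect_error(hosmer_lemeshow(c(0, 0.5), c("case", "control")),
               "strictly")
})

test_that("roc_points spans (0,0) to (1,1) and evaluate_scores reports all five", {
  co <- simulate_cohort(sim_config(seed = 17, n_cases = 60,
                                   n_controls = 100, n_snps = 15))
  prs <- compute_prs(co$genotypes, co$panel)
  gail <- score_cohort(co$subjects, co$rr_model, co$hazards)
  sc <- log_transform_scores(build_risk_scores(prs, gail, co$subjects))

  rp <- roc_points(sc$log_combined_5yr, sc$status)
  expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[1], 0)
  expect_equal(rp$fpr[nrow(rp)], 1); expect_equal(rp$tpr[nrow(rp)], 1)
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))

  ev <- evaluate_scores(sc)
  expect_identical(ev$score,
                   c("bcrat_5yr", "bcrat_lifetime", "snp_score",
                     "combined_5yr", "combined_lifetime"))
  expect_true(all(ev$opera_ci_low <= ev$opera_or &
                    ev$opera_or <= ev$opera_ci_high))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
})
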
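# Readers, validation and round-trip behaviour of the tabular inputs.

test_that("read_snp_panel computes mu and validates rows", {
  path <- write_tmp_csv(c("rsid,risk_allele,or,freq",
                          "rs0,A,1.0,0.3",
                          "rs1,G,2.0,0.5"))
  panel <- suppressMessages(read_snp_panel(path))
  expect_s3_class(panel, "snp_panel")
  expect_equal(panel$mu, c(1.0, 2.25))  # OR=1 -> 1; hand: .25 + 1 + 1

  expect_error(suppressMessages(read_snp_panel(write_tmp_csv(
    c("rsid,risk_allele,or,freq", "rs0,A,-1,0.3")))), "row")
  expect_error(suppressMessages(read_snp_panel(write_tmp_csv(
    c("rsid,risk_allele,or,freq", "rs0,A,1.2,1.3")))), "row")
  expect_error(snp_panel(c("rs0", "rs0"), c("A", "C"), c(1, 1), c(.1, .2)),
               "duplicate")
})

test_that("a 75-row panel file yields 75 entries", {
  panel <- simulate_panel(sim_config(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_snp_panel(panel, path)
  back <- suppressMessages(read_snp_panel(path))
  expect_equal(nrow(back), 75L)
  expect_equal(back$mu, panel$mu, tolerance = 1e-12)
})

test_that("read_genotype_matrix aligns, validates and marks missing", {
  panel <- tiny_panel()
  path <- write_tmp_csv(c("subject_id,rsA,rsB,rsC",
                          "s1,0,0,0", "s2,0,0,0", "s3,0,0,0"))
  g <- read_genotype_matrix(path, panel)
  expect_identical(dim(g), c(3L, 3L))
  expect_true(all(g == 0L) && !anyNA(g))

  # NA cell -> missing; empty cell too
  path <- write_tmp_csv(c("subject_id,rsA,rsB,rsC",
                          "s1,NA,1,", "s2,2,nan,0"))
  g <- read_genotype_matrix(path, panel)
  expect_true(is.na(g["s1", "rsA"]) && is.na(g["s1", "rsC"]))
  expect_true(is.na(g["s2", "rsB"]))
  expect_identical(g["s2", "rsA"], 2L)

  # shuffled file columns come back in panel order
  path <- write_tmp_csv(c("subject_id,rsC,rsA,rsB", "s1,2,0,1"))
  g <- read_genotype_matrix(path, panel)
  expect_identical(colnames(g), panel$rsid)
  expect_identical(as.integer(g["s1", ]), c(0L, 1L, 2L))

  # bad dosage names subject and rsid
  path <- write_tmp_csv(c("subject_id,rsA,rsB,rsC", "s9,0,3,1"))
  expect_error(read_genotype_matrix(path, panel), "s9.*rsB")

  # extra column dropped with warning
  path <- write_tmp_csv(c("subject_id,rsA,rsB,rsC,rsX", "s1,0,1,2,1"))
  expect_warning(g <- read_genotype_matrix(path, panel), "rsX")
  expect_identical(colnames(g), panel$rsid)
})

test_that("read_questionnaire types fields, excludes under-35s, codes unknowns", {
  path <- write_tmp_csv(c(
    "subject_id,status,age,n_first_degree_relatives,age_menarche,age_first_birth,n_biopsies,hyperplasia",
    "s1,case,45,1,12,22,,yes",
    "s2,control,34,0,13,25,1,no",        # excluded: age < 35
    "s3,control,60,2+,NA,nulliparous,0,",
    "s4,case,38,,14,NA,NA,NA"
  ))
  q <- suppressMessages(read_questionnaire(path))
  expect_identical(attr(q, "n_excluded_age"), 1L)
  expect_identical(q$subject_id, c("s1", "s3", "s4"))
  expect_true(is.na(q$n_biopsies[1]))        # blank -> UNKNOWN
  expect_identical(as.character(q$hyperplasia[1]), "yes")
  expect_true(q$nulliparous[2])
  expect_true(is.na(q$age_menarche[2]))
  expect_true(all(is.na(q[3, c("n_first_degree_relatives", "n_biopsies")])))

  expect_error(suppressMessages(read_questionnaire(write_tmp_csv(c(
    "subject_id,status,age,n_first_degree_relatives,age_menarche,age_first_birth,n_biopsies,hyperplasia",
    "s1,kase,45,0,12,22,0,no")))), "status")
  expect_error(suppressMessages(read_questionnaire(write_tmp_csv(c(
    "subject_id,status,age,n_first_degree_relatives,age_menarche,age_first_birth,n_biopsies,hyperplasia",
    "s1,case,forty,0,12,22,0,no")))), "age")

  empty <- write_tmp_csv(paste(
    "subject_id,status,age,n_first_degree_relatives,age_menarche",
    "age_first_birth,n_biopsies,hyperplasia", sep = ","))
  expect_warning(q0 <- read_questionnaire(empty), "empty")
  expect_identical(nrow(q0), 0L)
})

test_that("cohort round-trips through CSV byte-for-value", {
  co <- simulate_cohort(sim_config(seed = 11, n_cases = 40,
                                   n_controls = 70, n_snps = 12))
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  panel2 <- suppressMessages(read_snp_panel(paths["panel"]))
  geno2 <- read_genotype_matrix(paths["genotypes"], panel2)
  subj2 <- suppressMessages(read_questionnaire(paths["questionnaire"]))
  cfg2 <- read_risk_config(paths["config"])

  expect_identical(geno2, co$genotypes)
  expect_identical(subj2$status, co$subjects$status)
  expect_identical(subj2$n_first_degree_relatives,
                   co$subjects$n_first_degree_relatives)
  expect_identical(subj2$age, co$subjects$age)
  expect_identical(subj2$nulliparous, co$subjects$nulliparous)
  expect_identical(subj2$hyperplasia, co$subjects$hyperplasia)
  expect_equal(cfg2$hazards, co$hazards)
  expect_equal(cfg2$rr_model$log_rr, co$rr_model$log_rr)
})

test_that("permuting genotype CSV columns leaves downstream scores unchanged", {
  co <- simulate_cohort(sim_config(seed = 5, n_cases = 30, n_controls = 50,
                                   n_snps = 10))
  dir <- tempfile(); dir.create(dir)
  p1 <- file.path(dir, "g1.csv"); p2 <- file.path(dir, "g2.csv")
  write_genotype_matrix(co$genotypes, p1)
  perm <- sample(ncol(co$genotypes))
  write_genotype_matrix(co$genotypes[, perm], p2)
  g1 <- read_genotype_matrix(p1, co$panel)
  g2 <- read_genotype_matrix(p2, co$panel)
  expect_identical(g1, g2)
  expect_equal(compute_prs(g2, co$panel)$snp_score,
               compute_prs(g1, co$panel)$snp_score)
})

test_that("cohort_dataset enforces cross-references", {
  co <- simulate_cohort(sim_config(seed = 2, n_cases = 20, n_controls = 35,
                                   n_snps = 5))
  g <- co$genotypes
  rownames(g)[1] <- "ghost"
  expect_error(cohort_dataset(co$subjects, g, co$panel), "ghost")
  g2 <- co$genotypes[, -1, drop = FALSE]
  expect_error(cohort_dataset(co$subjects, g2, co$panel), "rsids")
})

test_that("shipped synthetic example panel and risk config load", {
  p <- system.file("extdata", "synthetic_panel_75snps.csv",
                   package = "combrisk")
  panel <- suppressMessages(read_snp_panel(p))
  expect_identical(nrow(panel), 75L)
  cfg <- read_risk_config(system.file("extdata",
                                      "synthetic_risk_config.json",
                                      package = "combrisk"))
  expect_s3_class(cfg$hazards, "hazard_table")
  expect_true(all(names(cfg$rr_model$log_rr) %in%
                    c("n_first_degree_relatives", "age_menarche",
                      "age_first_birth", "n_biopsies", "hyperplasia")))
})
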
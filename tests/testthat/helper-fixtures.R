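# Small fixtures built in code.

tiny_panel <- function() {
  snp_panel(rsid = c("rsA", "rsB", "rsC"),
            risk_allele = c("A", "G", "T"),
            or = c(1.0, 2.0, 0.8),
            freq = c(0.3, 0.5, 0.2))
}

flat_hazards <- function(h1 = 0.002, h2 = 0.01) {
  hazard_table(35, 90, h1, h2)
}

two_band_hazards <- function() {
  hazard_table(c(35, 60), c(60, 90), c(0.0015, 0.004), c(0.004, 0.02))
}

# A minimal questionnaire with explicit fields.
tiny_subjects <- function() {
  questionnaire_frame(
    subject_id = c("s1", "s2", "s3", "s4"),
    status = c("case", "control", "case", "control"),
    age = c(45L, 52L, 61L, 38L),
    n_first_degree_relatives = c("1", "0", NA, "2+"),
    age_menarche = c(11L, 13L, NA, 14L),
    age_first_birth = c(22L, NA, 31L, NA),
    nulliparous = c(FALSE, NA, FALSE, TRUE),
    n_biopsies = c(NA, 0L, 2L, NA),
    hyperplasia = c(NA, "no", "yes", NA)
  )
}

# questionnaire_frame is internal; reach it once for all test files
questionnaire_frame <- combrisk:::questionnaire_frame

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
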
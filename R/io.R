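# Readers, writers and validation for the three tabular inputs:
# SNP panel, genotype dosage matrix, BCRAT-style questionnaire.

MISSING_TOKENS <- c("", "na", "nan")

.is_missing_token <- function(x) {
  is.na(x) | tolower(trimws(as.character(x))) %in% MISSING_TOKENS
}

#' Construct a validated SNP panel
#'
#' A panel row holds one SNP's risk allele, per-allele odds ratio and
#' risk-allele frequency, plus the derived unscaled population-average risk
#' \eqn{\mu = (1-p)^2 + 2p(1-p)\,OR + p^2 OR^2}, i.e. the Hardy-Weinberg
#' expectation of the per-genotype relative risk.
#'
#' @param rsid character vector of unique SNP identifiers.
#' @param risk_allele single-character IUPAC bases.
#' @param or positive per-allele odds ratios.
#' @param freq risk-allele frequencies in `[0, 1]`.
#' @return A `data.frame` of class `snp_panel` with columns
#'   `rsid, risk_allele, or, freq, mu`.
#' @export
snp_panel <- function(rsid, risk_allele, or, freq) {
  rsid <- as.character(rsid)
  if (anyDuplicated(rsid)) {
    stop("duplicate rsid in panel: ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  }
  or <- as.numeric(or)
  freq <- as.numeric(freq)
  bad <- !is.finite(or) | or <= 0
  if (any(bad)) {
    stop("non-positive or malformed per-allele OR for: ",
         paste(rsid[bad], collapse = ", "))
  }
  bad <- !is.finite(freq) | freq < 0 | freq > 1
  if (any(bad)) {
    stop("risk-allele frequency outside [0, 1] for: ",
         paste(rsid[bad], collapse = ", "))
  }
  out <- data.frame(
    rsid = rsid,
    risk_allele = toupper(as.character(risk_allele)),
    or = or,
    freq = freq,
    mu = population_average_risk(freq, or),
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Read a SNP panel from CSV
#'
#' Expects header columns `rsid, risk_allele, or, freq`. Rows with a
#' malformed OR or frequency are rejected with an error naming the row.
#'
#' @param path path to the CSV file.
#' @return An `snp_panel` data frame (see [snp_panel()]).
#' @export
read_snp_panel <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("rsid", "risk_allele", "or", "freq")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("panel file missing column(s): ",
                         paste(miss, collapse = ", "))
  or <- suppressWarnings(as.numeric(raw$or))
  freq <- suppressWarnings(as.numeric(raw$freq))
  bad <- which(!is.finite(or) | or <= 0 | !is.finite(freq) |
                 freq < 0 | freq > 1)
  if (length(bad)) {
    stop("malformed OR or frequency at panel row(s) ",
         paste(bad, collapse = ", "), " (rsid ",
         paste(raw$rsid[bad], collapse = ", "), ")")
  }
  panel <- snp_panel(raw$rsid, raw$risk_allele, or, freq)
  message("read_snp_panel: ", nrow(panel), " SNP(s) from ", path)
  panel
}

#' Write a SNP panel to CSV
#' @param panel an `snp_panel`.
#' @param path output path.
#' @export
write_snp_panel <- function(panel, path) {
  utils::write.csv(panel[, c("rsid", "risk_allele", "or", "freq")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix from CSV
#'
#' The file has a `subject_id` column followed by one column per rsID;
#' cells are risk-allele counts 0/1/2 or a missing token (empty, `NA`,
#' `NaN`, case-insensitive). Columns are restricted to, and reordered to
#' match, the panel; file columns absent from the panel are dropped with a
#' warning.
#'
#' @param path path to the CSV file.
#' @param panel an `snp_panel` giving the column universe and order.
#' @return Integer matrix, subjects in rows (rownames = subject ids), SNPs
#'   in columns (colnames = panel rsids); `NA` marks missing dosages.
#' @export
read_genotype_matrix <- function(path, panel) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!"subject_id" %in% names(raw)) {
    stop("genotype file missing subject_id column")
  }
  ids <- raw$subject_id
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id in genotype file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  file_rsids <- setdiff(names(raw), "subject_id")
  extra <- setdiff(file_rsids, panel$rsid)
  if (length(extra)) {
    warning("dropping genotype column(s) absent from panel: ",
            paste(extra, collapse = ", "))
  }
  absent <- setdiff(panel$rsid, file_rsids)
  if (length(absent)) {
    stop("panel rsid(s) absent from genotype file: ",
         paste(absent, collapse = ", "))
  }
  m <- matrix(NA_integer_, nrow = length(ids), ncol = nrow(panel),
              dimnames = list(ids, panel$rsid))
  for (rs in panel$rsid) {
    col <- raw[[rs]]
    missing <- .is_missing_token(col)
    val <- suppressWarnings(as.integer(col))
    bad <- !missing & (is.na(val) | !(val %in% 0:2))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("dosage outside {0,1,2} for subject ", ids[i], " at ", rs,
           " (value '", col[i], "')")
    }
    val[missing] <- NA_integer_
    m[, rs] <- val
  }
  m
}

#' Write a genotype matrix to CSV
#' @param genotypes integer dosage matrix as from [read_genotype_matrix()].
#' @param path output path.
#' @export
write_genotype_matrix <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes),
                   genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# Map a raw first-degree-relatives cell to the {0, 1, 2+} category set.
.parse_fdr <- function(x) {
  out <- rep(NA_character_, length(x))
  missing <- .is_missing_token(x)
  x <- trimws(as.character(x))
  is2 <- !missing & (x == "2+" | suppressWarnings(as.numeric(x)) >= 2)
  is2[is.na(is2)] <- FALSE
  num <- suppressWarnings(as.numeric(x))
  out[!missing & !is2 & num == 0] <- "0"
  out[!missing & !is2 & num == 1] <- "1"
  out[is2] <- "2+"
  bad <- !missing & is.na(out)
  if (any(bad)) {
    stop("unparseable n_first_degree_relatives value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Read a BCRAT questionnaire table from CSV
#'
#' Expected columns: `subject_id, status, age, n_first_degree_relatives,
#' age_menarche, age_first_birth, n_biopsies, hyperplasia`. Status must be
#' coded `case`/`control`. Subjects younger than 35 are excluded (the
#' tool's validity restriction) and counted in the `n_excluded_age`
#' attribute. Empty/`NA`/`NaN` cells map to missing; a blank biopsy or
#' hyperplasia field is the accepted "unknown" response. The
#' `age_first_birth` column additionally accepts the token `nulliparous`.
#'
#' @param path path to the CSV file.
#' @return A `data.frame` of class `questionnaire` with typed columns
#'   (`status` a case/control factor, `nulliparous` logical) and attribute
#'   `n_excluded_age`.
#' @export
read_questionnaire <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("subject_id", "status", "age", "n_first_degree_relatives",
            "age_menarche", "age_first_birth", "n_biopsies", "hyperplasia")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("questionnaire missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("empty questionnaire file: ", path)
    out <- questionnaire_frame(character(0), character(0), integer(0),
                               character(0), integer(0), integer(0),
                               logical(0), integer(0), character(0))
    attr(out, "n_excluded_age") <- 0L
    return(out)
  }
  status <- tolower(trimws(raw$status))
  bad <- !status %in% c("case", "control")
  if (any(bad)) {
    stop("unknown status code(s): ",
         paste(unique(raw$status[bad]), collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(raw$age))
  if (any(!is.finite(age))) {
    stop("non-numeric age for subject(s): ",
         paste(raw$subject_id[!is.finite(age)], collapse = ", "))
  }
  age <- as.integer(age)

  afb_raw <- trimws(raw$age_first_birth)
  nullip <- tolower(afb_raw) == "nulliparous"
  afb_missing <- .is_missing_token(afb_raw) & !nullip
  afb <- suppressWarnings(as.integer(afb_raw))
  afb[nullip | afb_missing] <- NA_integer_
  nulliparous <- ifelse(afb_missing, NA, nullip)

  to_int <- function(col, what) {
    missing <- .is_missing_token(col)
    v <- suppressWarnings(as.integer(col))
    bad <- !missing & is.na(v)
    if (any(bad)) stop("non-integer ", what, " value(s): ",
                       paste(unique(col[bad]), collapse = ", "))
    v[missing] <- NA_integer_
    v
  }
  menarche <- to_int(raw$age_menarche, "age_menarche")
  biopsies <- to_int(raw$n_biopsies, "n_biopsies")
  if (any(!is.na(biopsies) & biopsies < 0)) stop("negative n_biopsies")
  hyp <- tolower(trimws(raw$hyperplasia))
  hyp[.is_missing_token(raw$hyperplasia)] <- NA_character_
  bad <- !is.na(hyp) & !hyp %in% c("yes", "no")
  if (any(bad)) stop("hyperplasia must be yes/no/blank, got: ",
                     paste(unique(hyp[bad]), collapse = ", "))

  keep <- age >= 35L
  n_excluded <- sum(!keep)
  if (n_excluded) {
    message("read_questionnaire: excluded ", n_excluded,
            " subject(s) under age 35")
  }
  out <- questionnaire_frame(
    subject_id = raw$subject_id[keep],
    status = status[keep],
    age = age[keep],
    n_first_degree_relatives = .parse_fdr(raw$n_first_degree_relatives)[keep],
    age_menarche = menarche[keep],
    age_first_birth = afb[keep],
    nulliparous = nulliparous[keep],
    n_biopsies = biopsies[keep],
    hyperplasia = hyp[keep]
  )
  attr(out, "n_excluded_age") <- n_excluded
  out
}

# Internal typed constructor shared by the reader and the simulator.
questionnaire_frame <- function(subject_id, status, age,
                                n_first_degree_relatives, age_menarche,
                                age_first_birth, nulliparous, n_biopsies,
                                hyperplasia) {
  if (anyDuplicated(subject_id)) {
    stop("duplicate subject_id in questionnaire: ",
         paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "))
  }
  out <- data.frame(
    subject_id = as.character(subject_id),
    status = factor(status, levels = c("control", "case")),
    age = as.integer(age),
    n_first_degree_relatives = factor(n_first_degree_relatives,
                                      levels = c("0", "1", "2+")),
    age_menarche = as.integer(age_menarche),
    age_first_birth = as.integer(age_first_birth),
    nulliparous = as.logical(nulliparous),
    n_biopsies = as.integer(n_biopsies),
    hyperplasia = factor(hyperplasia, levels = c("no", "yes")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("questionnaire", "data.frame")
  out
}

#' Write a questionnaire table to CSV
#'
#' Inverse of [read_questionnaire()]: nulliparous subjects are written with
#' the `nulliparous` token in `age_first_birth`; missing values as `NA`.
#'
#' @param subjects a `questionnaire` data frame.
#' @param path output path.
#' @export
write_questionnaire <- function(subjects, path) {
  afb <- as.character(subjects$age_first_birth)
  afb[!is.na(subjects$nulliparous) & subjects$nulliparous] <- "nulliparous"
  df <- data.frame(
    subject_id = subjects$subject_id,
    status = as.character(subjects$status),
    age = subjects$age,
    n_first_degree_relatives = as.character(subjects$n_first_degree_relatives),
    age_menarche = subjects$age_menarche,
    age_first_birth = afb,
    n_biopsies = subjects$n_biopsies,
    hyperplasia = as.character(subjects$hyperplasia),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Bundle subjects, genotypes and a panel into a consistent dataset
#'
#' Validates the cross-references: every genotyped subject appears in the
#' questionnaire and the genotype columns are exactly the panel rsIDs.
#'
#' @param subjects a `questionnaire` data frame.
#' @param genotypes integer dosage matrix.
#' @param panel an `snp_panel`.
#' @param hazards optional `hazard_table` carried along for convenience.
#' @param rr_model optional relative-risk model.
#' @param truth optional list of generator ground truth (synthetic cohorts).
#' @return A list of class `cohort_dataset`.
#' @export
cohort_dataset <- function(subjects, genotypes, panel,
                           hazards = NULL, rr_model = NULL, truth = NULL) {
  orphan <- setdiff(rownames(genotypes), subjects$subject_id)
  if (length(orphan)) {
    stop("genotyped subject(s) missing from questionnaire: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  if (!setequal(colnames(genotypes), panel$rsid)) {
    stop("genotype rsids do not match panel rsids")
  }
  genotypes <- genotypes[, panel$rsid, drop = FALSE]
  structure(list(subjects = subjects, genotypes = genotypes, panel = panel,
                 hazards = hazards, rr_model = rr_model, truth = truth),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", nrow(x$subjects), "subjects (",
      sum(x$subjects$status == "case", na.rm = TRUE), "cases /",
      sum(x$subjects$status == "control", na.rm = TRUE), "controls ),",
      nrow(x$panel), "SNPs\n")
  invisible(x)
}
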
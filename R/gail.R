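# Gail-model-style absolute risk engine.
#
# Coefficient-agnostic: the age-specific baseline incidence (the
# attributable-risk-adjusted composite hazard h1*) and competing mortality
# (h2) arrive as a user-supplied hazard table, and the questionnaire
# relative risks as a configurable log-RR model. Projection uses the
# standard piecewise-constant competing-risk formula over age bands.

#' Construct a validated hazard table
#'
#' Half-open age bands `[age_start, age_end)` must be contiguous,
#' non-overlapping and cover `[35, 90)`; hazards are per-year rates.
#'
#' @param age_start,age_end integer band edges in years.
#' @param incidence baseline breast-cancer hazard per year per band (h1*).
#' @param competing_mortality competing-mortality hazard per year (h2).
#' @return A `data.frame` of class `hazard_table`.
#' @export
hazard_table <- function(age_start, age_end, incidence, competing_mortality) {
  o <- order(age_start)
  age_start <- age_start[o]; age_end <- age_end[o]
  incidence <- incidence[o]; competing_mortality <- competing_mortality[o]
  if (any(age_end <= age_start)) stop("empty or inverted age band")
  if (age_start[1] != 35 || age_end[length(age_end)] != 90) {
    stop("hazard bands must cover [35, 90)")
  }
  if (length(age_start) > 1 &&
      any(age_start[-1] != age_end[-length(age_end)])) {
    stop("hazard bands must be contiguous and non-overlapping")
  }
  if (any(incidence < 0) || any(competing_mortality < 0)) {
    stop("hazards must be non-negative")
  }
  out <- data.frame(age_start = as.numeric(age_start),
                    age_end = as.numeric(age_end),
                    incidence = as.numeric(incidence),
                    competing_mortality = as.numeric(competing_mortality))
  class(out) <- c("hazard_table", "data.frame")
  out
}

# ---- relative-risk model ----------------------------------------------------

RR_VARIABLES <- c("n_first_degree_relatives", "age_menarche",
                  "age_first_birth", "n_biopsies", "hyperplasia")

#' Construct a relative-risk model
#'
#' `log_rr` is a named list with one element per questionnaire variable
#' (`n_first_degree_relatives`, `age_menarche`, `age_first_birth`,
#' `n_biopsies`, `hyperplasia`); each element is either a named numeric
#' vector of log relative risks per category, or — for an age-dependent
#' coefficient — a list with elements `"<50"` and `">=50"`, each a named
#' vector. Categories follow the Gail groupings (see [rr_categories()]).
#' An `UNKNOWN` category defaults to log-RR 0 (the accepted "unknown"
#' response is risk-neutral) unless the model names it explicitly.
#'
#' @param log_rr named list of per-variable log relative risks.
#' @param age_split age (years) at which age-dependent coefficients switch.
#' @return A list of class `rr_model`.
#' @export
rr_model <- function(log_rr, age_split = 50) {
  extra <- setdiff(names(log_rr), RR_VARIABLES)
  if (length(extra)) stop("unknown RR-model variable(s): ",
                          paste(extra, collapse = ", "))
  structure(list(log_rr = log_rr, age_split = age_split),
            class = "rr_model")
}

#' Questionnaire category labels used by the relative-risk model
#'
#' Maps the typed questionnaire columns onto the Gail category sets:
#' menarche `<12 / 12-13 / >=14`, first live birth
#' `<20 / 20-24 / 25-29 / >=30 / nulliparous`, relatives `0 / 1 / 2+`,
#' biopsies `0 / 1 / 2+`, hyperplasia `no / yes`. Any missing value maps
#' to `UNKNOWN`.
#'
#' @param subjects a `questionnaire` data frame.
#' @return A character data frame, one column per model variable.
#' @export
rr_categories <- function(subjects) {
  men <- ifelse(is.na(subjects$age_menarche), "UNKNOWN",
         ifelse(subjects$age_menarche < 12, "<12",
         ifelse(subjects$age_menarche <= 13, "12-13", ">=14")))
  afb <- ifelse(!is.na(subjects$nulliparous) & subjects$nulliparous,
                "nulliparous",
         ifelse(is.na(subjects$age_first_birth), "UNKNOWN",
         ifelse(subjects$age_first_birth < 20, "<20",
         ifelse(subjects$age_first_birth <= 24, "20-24",
         ifelse(subjects$age_first_birth <= 29, "25-29", ">=30")))))
  fdr <- as.character(subjects$n_first_degree_relatives)
  fdr[is.na(fdr)] <- "UNKNOWN"
  bio <- ifelse(is.na(subjects$n_biopsies), "UNKNOWN",
         ifelse(subjects$n_biopsies == 0, "0",
         ifelse(subjects$n_biopsies == 1, "1", "2+")))
  hyp <- as.character(subjects$hyperplasia)
  hyp[is.na(hyp)] <- "UNKNOWN"
  data.frame(n_first_degree_relatives = fdr, age_menarche = men,
             age_first_birth = afb, n_biopsies = bio, hyperplasia = hyp,
             stringsAsFactors = FALSE)
}

# Resolve one variable's coefficient vector for each subject and return the
# per-subject log-RR contribution. Unlisted UNKNOWN -> 0; any other
# unlisted category is an error naming the category.
.rr_contribution <- function(cats, coefs, ages, age_split, var) {
  lookup <- function(co, cat_vec) {
    out <- co[cat_vec]
    unlisted <- is.na(out) & !(cat_vec %in% names(co))
    if (any(unlisted & cat_vec != "UNKNOWN")) {
      stop("category '", cat_vec[unlisted & cat_vec != "UNKNOWN"][1],
           "' of ", var, " absent from RR model")
    }
    out[unlisted] <- 0
    unname(out)
  }
  if (is.list(coefs)) {
    if (!all(c("<50", ">=50") %in% names(coefs))) {
      stop("age-dependent coefficients for ", var,
           " must name '<50' and '>=50'")
    }
    ifelse(ages < age_split,
           lookup(coefs[["<50"]], cats),
           lookup(coefs[[">=50"]], cats))
  } else {
    lookup(coefs, cats)
  }
}

#' Questionnaire relative risk
#'
#' exp of the sum of the subject's category log-coefficients across the
#' model's variables; UNKNOWN categories contribute 0 unless the model says
#' otherwise.
#'
#' @param subjects a `questionnaire` data frame (one or more rows).
#' @param model an `rr_model`.
#' @return Numeric vector of relative risks, one per subject.
#' @export
relative_risk <- function(subjects, model) {
  cats <- rr_categories(subjects)
  total <- numeric(nrow(subjects))
  for (var in names(model$log_rr)) {
    total <- total + .rr_contribution(cats[[var]], model$log_rr[[var]],
                                      subjects$age, model$age_split, var)
  }
  exp(total)
}

# ---- absolute risk projection ----------------------------------------------

# Vectorized core: ages, horizons, rr recycled to common length.
.abs_risk_vec <- function(age, horizon, rr, hazards) {
  n <- max(length(age), length(horizon), length(rr))
  age <- rep_len(as.numeric(age), n)
  horizon <- rep_len(as.numeric(horizon), n)
  rr <- rep_len(as.numeric(rr), n)
  end_age <- age + horizon
  risk <- numeric(n)
  surv <- rep(1, n)
  for (j in seq_len(nrow(hazards))) {
    lo <- pmax(hazards$age_start[j], age)
    hi <- pmin(hazards$age_end[j], end_age)
    delta <- pmax(0, hi - lo)
    h1 <- hazards$incidence[j] * rr
    htot <- h1 + hazards$competing_mortality[j]
    active <- delta > 0 & htot > 0
    inc <- ifelse(active,
                  h1 / htot * (1 - exp(-htot * delta)) * surv,
                  0)
    risk <- risk + inc
    surv <- surv * exp(-htot * delta)
  }
  risk
}

#' Absolute risk over a horizon under competing mortality
#'
#' Piecewise-constant competing-risk projection: over each age band
#' intersected with `[age, age + horizon)`, the probability of a first
#' breast-cancer event is
#' \eqn{\frac{h_1 rr}{h_1 rr + h_2}\,(1 - e^{-(h_1 rr + h_2)\Delta})}
#' times the probability of having survived both causes through the
#' preceding bands; the band contributions are summed.
#'
#' @param age attained age in whole years, at least 35.
#' @param horizon projection length in years, positive, with
#'   `age + horizon <= 90`.
#' @param rr questionnaire relative risk multiplying the baseline
#'   incidence.
#' @param hazards a `hazard_table`.
#' @return Absolute risk in `[0, 1]`.
#' @export
absolute_risk <- function(age, horizon, rr, hazards) {
  if (any(age < 35)) {
    stop("absolute risk is restricted to women aged 35 years or older")
  }
  if (any(horizon <= 0)) stop("projection horizon must be positive")
  if (any(age + horizon > 90 + 1e-9)) {
    stop("projection must end by age 90 (lifetime horizon)")
  }
  if (any(rr <= 0)) stop("relative risk must be positive")
  .abs_risk_vec(age, horizon, rr, hazards)
}

#' Project 5-year and lifetime absolute risks for a cohort
#'
#' The 5-year risk uses horizon `min(5, 90 - age)`; the lifetime risk runs
#' to age 90. For a subject at age 89 both horizons collapse to one year.
#'
#' @param subjects a `questionnaire` data frame, ages in `[35, 89]`.
#' @param model an `rr_model`.
#' @param hazards a `hazard_table`.
#' @return A `data.frame` with columns `subject_id, rr, five_year,
#'   lifetime`.
#' @export
score_cohort <- function(subjects, model, hazards) {
  if (any(subjects$age > 89)) {
    stop("cohort projection requires age <= 89 (positive lifetime horizon)")
  }
  rr <- relative_risk(subjects, model)
  data.frame(
    subject_id = subjects$subject_id,
    rr = rr,
    five_year = absolute_risk(subjects$age, pmin(5, 90 - subjects$age),
                              rr, hazards),
    lifetime = absolute_risk(subjects$age, 90 - subjects$age, rr, hazards),
    stringsAsFactors = FALSE
  )
}

# ---- configuration file ----------------------------------------------------

#' Read a hazard-table + RR-model configuration from JSON
#'
#' The file holds two top-level keys: `hazards` (arrays `age_start`,
#' `age_end`, `incidence`, `competing_mortality`) and `log_rr` (one object
#' per variable mapping category to log relative risk, or objects `"<50"` /
#' `">=50"` of those for age-dependent coefficients), plus optional
#' `age_split`.
#'
#' @param path path to the JSON config.
#' @return `list(hazards = <hazard_table>, rr_model = <rr_model>)`.
#' @export
read_risk_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$hazards) || is.null(cfg$log_rr)) {
    stop("risk config must contain 'hazards' and 'log_rr'")
  }
  h <- cfg$hazards
  hz <- hazard_table(h$age_start, h$age_end, h$incidence,
                     h$competing_mortality)
  to_named <- function(x) {
    if (is.list(x) && any(c("<50", ">=50") %in% names(x))) {
      lapply(x, function(v) unlist(v))
    } else {
      unlist(x)
    }
  }
  model <- rr_model(lapply(cfg$log_rr, to_named),
                    age_split = if (is.null(cfg$age_split)) 50
                                else cfg$age_split)
  list(hazards = hz, rr_model = model)
}

#' Write a hazard-table + RR-model configuration to JSON
#' @param hazards a `hazard_table`.
#' @param model an `rr_model`.
#' @param path output path.
#' @export
write_risk_config <- function(hazards, model, path) {
  cfg <- list(
    hazards = list(age_start = hazards$age_start,
                   age_end = hazards$age_end,
                   incidence = hazards$incidence,
                   competing_mortality = hazards$competing_mortality),
    log_rr = lapply(model$log_rr, function(x) {
      if (is.list(x)) lapply(x, as.list) else as.list(x)
    }),
    age_split = model$age_split
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
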
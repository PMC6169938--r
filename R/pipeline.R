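# End-to-end orchestration and the command-line entry point.

# Tiny polynomial hash of a string, for config provenance in the run log.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full risk-assessment pipeline
#'
#' Reads the panel, genotypes, questionnaire and risk config; computes the
#' SNP score, 5-year/lifetime clinical risks and combined scores; evaluates
#' OPERA, AUC (with paired DeLong comparison of combined vs clinical) and
#' Hosmer-Lemeshow calibration; reclassifies at both guideline thresholds
#' with NRI; and writes `scores.csv`, `evaluation.csv`,
#' `reclassification.csv`, `summary.json` and `run.log` to `out_dir`. On
#' any error, partially written outputs are removed and the error is
#' re-raised.
#'
#' @param panel,genotypes,questionnaire,config input file paths (CSV, CSV,
#'   CSV, JSON risk config).
#' @param out_dir output directory (created if needed).
#' @param threshold_5yr,threshold_lifetime guideline cutoffs (defaults
#'   0.0166 and 0.20).
#' @param seed RNG seed (used only by the bootstrap CI).
#' @param bootstrap_ci use a seeded bootstrap (2000 resamples) for the NRI
#'   CI instead of the asymptotic formula.
#' @param opera_method OPERA age-adjustment layout, see [opera()].
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(panel, genotypes, questionnaire, config, out_dir,
                         threshold_5yr = 0.0166, threshold_lifetime = 0.20,
                         seed = 1, bootstrap_ci = FALSE,
                         opera_method = c("covariate", "residualize")) {
  opera_method <- match.arg(opera_method)
  if (threshold_5yr <= 0 || threshold_5yr >= 1 ||
      threshold_lifetime <= 0 || threshold_lifetime >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("scores.csv", "evaluation.csv",
                                  "reclassification.csv", "summary.json",
                                  "run.log"))
  names(outputs) <- c("scores", "evaluation", "reclassification",
                      "summary", "log")
  written <- character(0)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  run <- function() {
    cfg_echo <- jsonlite::toJSON(list(
      panel = panel, genotypes = genotypes, questionnaire = questionnaire,
      config = config, threshold_5yr = threshold_5yr,
      threshold_lifetime = threshold_lifetime, seed = seed,
      bootstrap_ci = bootstrap_ci, opera_method = opera_method
    ), auto_unbox = TRUE)
    note("run_pipeline start; seed=", seed,
         " config_hash=", .fnv1a(as.character(cfg_echo)))

    pnl <- read_snp_panel(panel)
    note("panel: ", nrow(pnl), " SNPs")
    subj <- read_questionnaire(questionnaire)
    note("questionnaire: ", nrow(subj), " subjects (",
         attr(subj, "n_excluded_age"), " excluded under 35)")
    geno <- read_genotype_matrix(genotypes, pnl)
    note("genotypes: ", nrow(geno), " x ", ncol(geno))
    rc <- read_risk_config(config)

    ds <- cohort_dataset(subj, geno, pnl,
                         hazards = rc$hazards, rr_model = rc$rr_model)
    prs <- compute_prs(ds$genotypes, ds$panel)
    gail <- score_cohort(ds$subjects, rc$rr_model, rc$hazards)
    scores <- log_transform_scores(build_risk_scores(prs, gail,
                                                     ds$subjects))
    note("scored: ", nrow(scores), " subjects")
    utils::write.csv(scores, outputs["scores"], row.names = FALSE)
    written <<- c(written, outputs["scores"])

    ev <- evaluate_scores(scores, method = opera_method)
    # paired AUC comparison and calibration per horizon
    cmp5 <- auc_compare(scores$log_combined_5yr, scores$log_bcrat_5yr,
                        scores$status)
    cmpL <- auc_compare(scores$log_combined_lifetime,
                        scores$log_bcrat_lifetime, scores$status)
    hl <- lapply(SCORE_COLUMNS, function(col) {
      fit <- stats::glm(I(status == "case") ~ scores[[paste0("log_", col)]]
                        + age, family = stats::binomial(), data = scores)
      res <- suppressWarnings(hosmer_lemeshow(stats::fitted(fit),
                                              scores$status))
      data.frame(score = col, hl_chisq = res$chisq, hl_df = res$df,
                 hl_p = res$p_value)
    })
    ev <- merge(ev, do.call(rbind, hl), by = "score", sort = FALSE)
    utils::write.csv(ev, outputs["evaluation"], row.names = FALSE)
    written <<- c(written, outputs["evaluation"])
    note("evaluation written (", nrow(ev), " scores)")

    reclass_one <- function(clinical, combined, threshold, label) {
      tab <- cross_tabulate(clinical, combined, scores$status, threshold)
      n <- if (bootstrap_ci) {
        nri_bootstrap(clinical, combined, scores$status, threshold,
                      seed = seed)
      } else {
        nri(tab)
      }
      fr <- reclassified_fractions(tab)
      list(label = label, table = tab, nri = n, fractions = fr)
    }
    r5 <- reclass_one(scores$bcrat_5yr, scores$combined_5yr,
                      threshold_5yr, "five_year")
    rL <- reclass_one(scores$bcrat_lifetime, scores$combined_lifetime,
                      threshold_lifetime, "lifetime")
    flat <- function(r) {
      data.frame(
        horizon = r$label, threshold = r$table$threshold,
        stratum = rep(c("case", "control"), each = 4),
        clinical = rep(c("low", "low", "high", "high"), 2),
        combined = rep(c("low", "high", "low", "high"), 2),
        count = c(t(r$table$case_counts), t(r$table$control_counts)),
        nri = r$nri$nri, nri_ci_low = r$nri$ci_low,
        nri_ci_high = r$nri$ci_high,
        stringsAsFactors = FALSE
      )
    }
    utils::write.csv(rbind(flat(r5), flat(rL)),
                     outputs["reclassification"], row.names = FALSE)
    written <<- c(written, outputs["reclassification"])
    note("reclassification written; NRI 5yr=",
         sprintf("%.3f", r5$nri$nri), " lifetime=",
         sprintf("%.3f", rL$nri$nri))

    summary <- list(
      n_subjects = nrow(scores),
      n_cases = sum(scores$status == "case"),
      n_controls = sum(scores$status == "control"),
      evaluation = ev,
      auc_comparison = list(five_year = cmp5, lifetime = cmpL),
      nri = list(
        five_year = list(threshold = threshold_5yr, nri = r5$nri$nri,
                         ci_low = r5$nri$ci_low, ci_high = r5$nri$ci_high,
                         components = as.list(r5$nri$components)),
        lifetime = list(threshold = threshold_lifetime, nri = rL$nri$nri,
                        ci_low = rL$nri$ci_low, ci_high = rL$nri$ci_high,
                        components = as.list(rL$nri$components))
      ),
      config = jsonlite::fromJSON(cfg_echo)
    )
    jsonlite::write_json(summary, outputs["summary"], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    written <<- c(written, outputs["summary"])
    writeLines(log_lines, outputs["log"])
    summary
  }

  tryCatch(invisible(run()), error = function(e) {
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
}

# ---- command-line interface -------------------------------------------------

.cli_parse <- function(args) {
  opts <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        opts[[gsub("-", "_", kv[1])]] <- paste(kv[-1], collapse = "=")
      } else if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[gsub("-", "_", key)]] <- args[i + 1L]
        i <- i + 1L
      } else {
        opts[[gsub("-", "_", key)]] <- TRUE
      }
    } else {
      positional <- c(positional, a)
    }
    i <- i + 1L
  }
  list(opts = opts, positional = positional)
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

.cli_usage <- function() {
  cat(
"usage: combrisk <subcommand> [--flag value ...]\n\n",
"subcommands:\n",
"  simulate        --out DIR [--seed N] [--n-cases N] [--n-controls N]\n",
"                  [--n-snps N] [--genetic-effect X] [--clinical-effect X]\n",
"  score           --panel F --genotypes F --questionnaire F --hazards F\n",
"                  --out DIR\n",
"  run             same inputs as score, plus [--threshold-5yr X]\n",
"                  [--threshold-lifetime X] [--seed N] [--bootstrap-ci]\n",
"  nri-from-table  --cases a,b,c,d --controls a,b,c,d (row-major\n",
"                  low->low,low->high,high->low,high->high)\n", sep = "")
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a seeded synthetic cohort's input
#' files), `score`/`evaluate`/`reclassify`/`run` (the pipeline; the first
#' three are aliases of `run`, which always writes every artifact), and
#' `nri-from-table` (reproduce a published NRI from eight printed counts).
#' Installed as the `combrisk` script under `inst/exec`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process's trailing arguments).
#' @return Integer exit status, invisibly (0 on success).
#' @export
crp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
    .cli_usage()
    return(invisible(0L))
  }
  cmd <- args[1]
  parsed <- .cli_parse(args[-1])
  o <- parsed$opts
  status <- tryCatch({
    switch(cmd,
      "simulate" = {
        if (is.null(o$out)) stop("simulate requires --out")
        cfg <- sim_config(
          n_snps = .cli_num(o, "n_snps", 75),
          n_cases = .cli_num(o, "n_cases", 319),
          n_controls = .cli_num(o, "n_controls", 559),
          genetic_effect = .cli_num(o, "genetic_effect", 1),
          clinical_effect = .cli_num(o, "clinical_effect", 1),
          seed = as.integer(.cli_num(o, "seed", 1))
        )
        paths <- write_cohort(simulate_cohort(cfg), o$out)
        cat("wrote:", paste(basename(paths), collapse = ", "),
            "->", o$out, "\n")
        0L
      },
      "score" = , "evaluate" = , "reclassify" = , "run" = {
        need <- c("panel", "genotypes", "questionnaire", "hazards", "out")
        miss <- need[vapply(need, function(k) is.null(o[[k]]), logical(1))]
        if (length(miss)) stop(cmd, " requires --",
                               paste(miss, collapse = " --"))
        run_pipeline(
          panel = o$panel, genotypes = o$genotypes,
          questionnaire = o$questionnaire, config = o$hazards,
          out_dir = o$out,
          threshold_5yr = .cli_num(o, "threshold_5yr", 0.0166),
          threshold_lifetime = .cli_num(o, "threshold_lifetime", 0.20),
          seed = as.integer(.cli_num(o, "seed", 1)),
          bootstrap_ci = isTRUE(o$bootstrap_ci)
        )
        0L
      },
      "nri-from-table" = {
        if (is.null(o$cases) || is.null(o$controls)) {
          stop("nri-from-table requires --cases and --controls")
        }
        parse4 <- function(s) {
          v <- as.numeric(strsplit(s, ",")[[1]])
          if (length(v) != 4L) stop("expected four comma-separated counts")
          v
        }
        res <- nri_from_table(parse4(o$cases), parse4(o$controls))
        print(res)
        0L
      },
      {
        .cli_usage()
        stop("unknown subcommand: ", cmd)
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
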
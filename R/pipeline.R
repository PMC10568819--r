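# End-to-end orchestration: synthetic or supplied data in, Table-1/Table-2
# style reports out, with a manifest tying outputs to config + seed.

PIPELINE_PREDICTORS <- c("bmi", "pct_over_median", "medicaid",
                         "education_years", "income", "minority",
                         "family_size", "age", "sex_code")

#' Read a plain-text `key: value` configuration file
#'
#' Lines of the form `key: value`; blank lines and `#` comments ignored.
#' Values are parsed as numbers where possible, otherwise kept as strings.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_kv_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("malformed config line: '%s' (expected 'key: value')", ln),
           call. = FALSE)
    }
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}

# Assemble the per-participant analysis dataset from scored profiles, QC,
# demographics and anthropometrics.
build_analysis_dataset <- function(cohort, profiles, llr_amount,
                                   reference = synthetic_lms_reference()) {
  qc <- qc_report(profiles, llr_amount = llr_amount)
  wide <- split(profiles, profiles$participant_id)
  auc <- vapply(wide, function(sub) {
    sub <- sub[order(sub$delay_days), ]
    auc_ordinal(dd_profile(sub$participant_id[1], sub$delay_days,
                           sub$indifference_point, llr_amount))$auc_ord
  }, numeric(1))
  auc_df <- data.frame(participant_id = names(auc), auc_ord = unname(auc),
                       stringsAsFactors = FALSE)
  d <- merge(cohort, auc_df, by = "participant_id")
  d <- merge(d, qc[, c("participant_id", "systematic",
                       "criterion1_violations", "criterion2_violation")],
             by = "participant_id")
  d <- score_anthropometrics(d, reference)
  codes <- encode_covariates(d$race, d$ethnicity, d$insurance, d$sex)
  d$medicaid <- codes$medicaid
  d$minority <- codes$minority
  d$sex_code <- codes$sex_code
  d$income_category <- categorize_income(d$income)
  d[order(d$family_id, d$member_role, decreasing = c(FALSE, TRUE),
          method = "radix"), ]
}

# Descriptives in the shape of a baseline characteristics table: one row per
# (role, variable), columns for the all / systematic / non-systematic
# samples and a systematic-vs-non-systematic difference p-value (Welch t for
# continuous, chi-square for proportions).
descriptives_table <- function(dataset) {
  member_vars <- c(sex_male = "binary", minority = "binary",
                   pct_over_median = "cont", age = "cont", auc_ord = "cont")
  family_vars <- c(medicaid = "binary", education_years = "cont",
                   income = "cont", family_size = "cont", bmi = "cont",
                   zbmi = "cont")
  dataset$sex_male <- as.integer(dataset$sex_code == 1L)
  rows <- list()
  fmt <- function(x, kind) {
    x <- x[is.finite(x)]
    if (kind == "binary") sprintf("%.1f%%", 100 * mean(x))
    else sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  }
  pdiff <- function(x, g, kind) {
    ok <- !is.na(x)
    x <- x[ok]; g <- g[ok]
    if (length(unique(g)) < 2L) return(NA_real_)
    if (kind == "binary") {
      tab <- table(factor(x, c(0, 1)), g)
      tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
               error = function(e) NA_real_)
    } else {
      tryCatch(stats::t.test(x ~ g)$p.value, error = function(e) NA_real_)
    }
  }
  add_rows <- function(sub, role, vars) {
    sys <- sub$systematic == 1
    n_row <- data.frame(role = role, variable = "N",
                        all = as.character(nrow(sub)),
                        systematic = as.character(sum(sys)),
                        non_systematic = as.character(sum(!sys)),
                        p_sys_vs_nonsys = NA_real_, stringsAsFactors = FALSE)
    var_rows <- lapply(names(vars), function(v) {
      data.frame(role = role, variable = v,
                 all = fmt(sub[[v]], vars[[v]]),
                 systematic = fmt(sub[[v]][sys], vars[[v]]),
                 non_systematic = fmt(sub[[v]][!sys], vars[[v]]),
                 p_sys_vs_nonsys = pdiff(sub[[v]], sys, vars[[v]]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(list(n_row), var_rows))
  }
  for (role in c("parent", "child")) {
    sub <- dataset[dataset$member_role == role, , drop = FALSE]
    vars <- if (role == "parent") c(member_vars, family_vars) else member_vars
    rows[[role]] <- add_rows(sub, role, vars)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes scoring, QC, ordinal AUC, anthropometric scoring, covariate
#' coding, and the correlation / stacked-model battery (both the all-data
#' and systematic-only samples, with and without covariates), writing a
#' descriptives table, results tables, model dump, QC report and a run
#' manifest to `out_dir`.
#'
#' In `synthetic` mode a cohort is generated from `synthetic_config()`
#' overridden by entries of `config`; in `data` mode `config` must name
#' `choices_csv` (per-trial log) and `demographics_csv` files, which are
#' validated before any model runs.
#'
#' @param config Named list of settings, or a path to a `key: value` file
#'   ([read_kv_config()]). Recognised keys: any [synthetic_config()]
#'   argument; `llr_amount`; `fdr_q`; in data mode `choices_csv`,
#'   `demographics_csv`.
#' @param mode `"synthetic"` or `"data"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the config seed when not `NULL`.
#' @return Invisibly, a list with the analysis dataset, the results tables
#'   (plain and covariate-adjusted), descriptives, QC report and manifest.
#' @export
run_pipeline <- function(config = list(), mode = c("synthetic", "data"),
                         out_dir = "dd_run", seed = NULL) {
  mode <- match.arg(mode)
  if (is.character(config) && length(config) == 1L) {
    config <- read_kv_config(config)
  }
  stopifnot(is.list(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  llr <- config$llr_amount %||% 100
  fdr_q <- config$fdr_q %||% 0.10
  task <- task_config(llr_amount = llr)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character()

  if (mode == "synthetic") {
    syn_args <- config[intersect(names(config),
                                 names(formals(synthetic_config)))]
    scfg <- do.call(synthetic_config, syn_args)
    cohort <- generate_cohort(scfg)
    raw <- generate_raw_choices(cohort, task, scfg)
    trials <- raw$trials
    profiles <- raw$profiles
  } else {
    for (key in c("choices_csv", "demographics_csv")) {
      if (is.null(config[[key]]) || !file.exists(config[[key]])) {
        stop(sprintf("data mode requires config key '%s' naming an existing file",
                     key), call. = FALSE)
      }
    }
    inputs <- c(config$choices_csv, config$demographics_csv)
    trials <- utils::read.csv(config$choices_csv, stringsAsFactors = FALSE)
    cohort <- utils::read.csv(config$demographics_csv,
                              stringsAsFactors = FALSE)
    validate_input_tables(trials, cohort)
    profiles <- score_all_logs(trials, task)
  }

  dataset <- build_analysis_dataset(cohort, profiles, llr)
  qc <- qc_report(profiles, llr_amount = llr)
  desc <- descriptives_table(dataset)
  stacked_in <- dataset
  results <- build_results_tables(stacked_in, PIPELINE_PREDICTORS, q = fdr_q,
                                  with_covariates = FALSE)
  results_cov <- build_results_tables(stacked_in, PIPELINE_PREDICTORS,
                                      q = fdr_q, with_covariates = TRUE)

  paths <- c(
    choices = "choices.csv", profiles = "profiles.csv",
    qc = "qc_report.csv", dataset = "analysis_dataset.csv",
    descriptives = "descriptives.csv",
    correlations = "correlations.csv", interactions = "interactions.csv",
    correlations_cov = "correlations_covariate_adjusted.csv",
    interactions_cov = "interactions_covariate_adjusted.csv",
    model_dump = "model_dump.txt", manifest = "manifest.json"
  )
  paths[] <- file.path(out_dir, paths)
  wcsv <- function(x, p) utils::write.csv(x, p, row.names = FALSE)
  wcsv(trials, paths["choices"])
  wcsv(profiles, paths["profiles"])
  wcsv(qc, paths["qc"])
  drop_cols <- intersect(c("fit"), names(dataset))
  wcsv(dataset[, setdiff(names(dataset), drop_cols)], paths["dataset"])
  wcsv(desc, paths["descriptives"])
  wcsv(results$correlations, paths["correlations"])
  wcsv(results$interactions, paths["interactions"])
  wcsv(results_cov$correlations, paths["correlations_cov"])
  wcsv(results_cov$interactions, paths["interactions_cov"])
  dump_models(c(results$models, results_cov$models), paths["model_dump"])

  manifest <- list(
    package = "dyadDD",
    version = as.character(utils::packageVersion("dyadDD")),
    mode = mode,
    seed = config$seed %||% NA,
    config = config[setdiff(names(config), NULL)],
    task = unclass(task),
    fdr_tests = results$m,
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else list(),
    outputs = as.list(basename(paths))
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(dataset = dataset, results = results,
                 results_covariates = results_cov, descriptives = desc,
                 qc = qc, manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Score every participant's choice log; aborts with the participant and
# delay/trial on the first inconsistent log.
score_all_logs <- function(trials, task) {
  rows <- lapply(split(trials, trials$participant_id), function(sub) {
    prof <- tryCatch(score_choice_log(sub, task), error = function(e) {
      stop(sprintf("participant %s: %s", sub$participant_id[1],
                   conditionMessage(e)), call. = FALSE)
    })
    out <- data.frame(participant_id = prof$participant_id,
                      delay_days = prof$delays,
                      indifference_point = prof$points,
                      stringsAsFactors = FALSE)
    if ("member_role" %in% names(sub)) out$member_role <- sub$member_role[1]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_input_tables <- function(trials, cohort) {
  need_t <- c("participant_id", "delay_days", "trial_index",
              "immediate_amount", "chose_immediate")
  need_c <- c("family_id", "participant_id", "member_role", "age", "sex",
              "age_months", "height_cm", "weight_kg", "race", "ethnicity",
              "insurance", "income", "education_years", "family_size")
  miss_t <- setdiff(need_t, names(trials))
  miss_c <- setdiff(need_c, names(cohort))
  if (length(miss_t)) {
    stop(sprintf("choices file missing columns: %s",
                 paste(miss_t, collapse = ", ")), call. = FALSE)
  }
  if (length(miss_c)) {
    stop(sprintf("demographics file missing columns: %s",
                 paste(miss_c, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(trials$immediate_amount) |
                 !trials$chose_immediate %in% c(0, 1))
  if (length(bad)) {
    stop(sprintf("choices file row %d is malformed (offer '%s', choice '%s')",
                 bad[1], trials$immediate_amount[bad[1]],
                 trials$chose_immediate[bad[1]]), call. = FALSE)
  }
  orphans <- setdiff(trials$participant_id, cohort$participant_id)
  if (length(orphans)) {
    stop(sprintf("choices file has participants absent from demographics: %s",
                 paste(utils::head(orphans, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

dump_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(models)) {
    mod <- models[[nm]]
    writeLines(sprintf("== %s ==", nm), con)
    if (is.null(mod)) {
      writeLines("  (model could not be fit)", con)
      next
    }
    writeLines(utils::capture.output(print(mod)), con)
    writeLines("", con)
  }
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort + choice logs), `score`
#' (choice log to indifference profiles), `qc` (profiles to QC report),
#' `analyze` (analysis dataset to results tables), `run-all` (full
#' pipeline). Common flags: `--config PATH`, `--seed INT`, `--out DIR`,
#' `--mode synthetic|data`, `--in PATH` (input file for `score`, `qc`,
#' `analyze`). Returns 0 on success and 1 on error; the installed `dyaddd`
#' script uses the return value as the process exit status.
#'
#' @param args Character vector of command-line arguments; defaults to the
#'   process arguments.
#' @return Integer exit status, invisibly.
#' @export
dd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      stop("usage: dyaddd <simulate|score|qc|analyze|run-all> [--config PATH] [--seed INT] [--out DIR] [--mode synthetic|data] [--in PATH]",
           call. = FALSE)
    }
    cmd <- args[1]
    opts <- parse_cli_flags(args[-1])
    seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
    out <- opts$out %||% "dd_run"
    cfg <- if (!is.null(opts$config)) read_kv_config(opts$config) else list()
    switch(cmd,
      "run-all" = {
        run_pipeline(cfg, mode = opts$mode %||% "synthetic",
                     out_dir = out, seed = seed)
      },
      "simulate" = {
        if (!is.null(seed)) cfg$seed <- seed
        scfg <- do.call(synthetic_config,
                        cfg[intersect(names(cfg),
                                      names(formals(synthetic_config)))])
        cohort <- generate_cohort(scfg)
        raw <- generate_raw_choices(cohort, task_config(), scfg)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(cohort, file.path(out, "cohort.csv"),
                         row.names = FALSE)
        utils::write.csv(raw$trials, file.path(out, "choices.csv"),
                         row.names = FALSE)
      },
      "score" = {
        trials <- utils::read.csv(opts[["in"]], stringsAsFactors = FALSE)
        prof <- score_all_logs(trials, task_config())
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(prof, file.path(out, "profiles.csv"),
                         row.names = FALSE)
      },
      "qc" = {
        prof <- utils::read.csv(opts[["in"]], stringsAsFactors = FALSE)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(qc_report(prof), file.path(out, "qc_report.csv"),
                         row.names = FALSE)
      },
      "analyze" = {
        dataset <- utils::read.csv(opts[["in"]], stringsAsFactors = FALSE)
        res <- build_results_tables(dataset, intersect(PIPELINE_PREDICTORS,
                                                       names(dataset)))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(res$correlations,
                         file.path(out, "correlations.csv"),
                         row.names = FALSE)
        utils::write.csv(res$interactions,
                         file.path(out, "interactions.csv"),
                         row.names = FALSE)
      },
      stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) {
      stop(sprintf("malformed flag '%s' (expected --flag value)", a),
           call. = FALSE)
    }
    opts[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
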
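## Orchestration: simulate a dataset to disk, run the full analysis to a
## report bundle, validate an on-disk dataset. Every run writes a manifest
## (config snapshot, seed, file digests, timestamps) so results are
## auditable and reruns byte-reproducible for deterministic stages.

config_snapshot <- function(config) {
  list(study_start = format(config$study_start),
       study_end = format(config$study_end),
       lookback_days = config$lookback_days,
       followup_days = config$followup_days,
       adult_age_min = config$adult_age_min,
       national_population = config$national_population,
       code_set = list(dvt_codes = config$code_set$dvt_codes,
                       pe_codes = config$code_set$pe_codes),
       rule = unclass(config$rule))
}

write_manifest <- function(out_dir, files, config, seed = NULL,
                           extra = list()) {
  manifest <- c(list(
    package = "vteclaims",
    version = as.character(packageVersion("vteclaims")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config_snapshot(config),
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))),
    extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Simulate a dataset and write it to disk
#'
#' Writes `persons.csv`, `claims.csv`, `stays.csv`, the truth tables
#' (`truth_events.csv`, `truth_index.csv`, `truth_covariates.csv`) and a
#' manifest with file digests.
#'
#' @param params a [sim_params()] (its seed drives all randomness).
#' @param out_dir output directory.
#' @param config a [study_config()].
#' @return invisibly, the simulation result of [simulate_claims()].
#' @export
run_simulation <- function(params, out_dir, config = study_config()) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_claims(params, config)
  files <- write_claims_dataset(sim$dataset, out_dir)
  tf <- file.path(out_dir, c("truth_events.csv", "truth_index.csv",
                             "truth_covariates.csv"))
  fwrite(sim$truth$events, tf[1])
  fwrite(sim$truth$index, tf[2])
  fwrite(sim$truth$covariates, tf[3])
  write_manifest(out_dir, c(files, tf), config, seed = params$seed,
                 extra = list(n_persons = params$n_persons))
  invisible(sim)
}

followup_report_json <- function(rep) {
  prop <- function(p) if (is.null(p)) NULL else unclass(p)
  list(
    n_by_group = as.list(rep$n_by_group),
    recurrence = list(
      table = as.data.frame.matrix(rep$recurrence$table),
      proportions = lapply(rep$recurrence$proportions, prop),
      chi2 = rep$recurrence$chi2),
    recurrence_frequency = as.data.frame.matrix(rep$recurrence_frequency),
    recurrence_type = list(
      table = if (is.null(rep$recurrence_type$table)) NULL else
        as.data.frame.matrix(rep$recurrence_type$table),
      fisher_p = rep$recurrence_type$fisher_p),
    mortality = list(deaths = as.list(rep$mortality$deaths),
                     proportions = lapply(rep$mortality$proportions, prop),
                     dvt_setting_chi2 = rep$mortality$dvt_setting_chi2),
    km_recurrence_at_months = rep$km_recurrence$at_months,
    km_death_at_months = rep$km_death$at_months,
    notices = rep$notices)
}

model_result_json <- function(m) {
  if (is.null(m)) return(NULL)
  list(terms = m$terms, retained = m$retained, converged = m$converged,
       n = m$n, notice = m$notice)
}

#' Run the full analysis pipeline
#'
#' Case finding, adjudication, incidence estimation, follow-up statistics
#' and the two risk models, on an in-memory dataset or a directory written
#' by [run_simulation()]. When `out_dir` is given, writes `incidence.csv`,
#' `recurrence.csv`, `mortality.csv`, `km_recurrence.csv`, `km_death.csv`,
#' `cox_recurrence.csv`, `logistic_hospitalisation.csv`, a consolidated
#' `report.json`, and a manifest.
#'
#' @param data a `claims_dataset` or a directory containing
#'   `persons.csv`/`claims.csv`/`stays.csv`.
#' @param config a [study_config()].
#' @param out_dir optional output directory.
#' @param risk_candidates covariate names screened by the two risk models
#'   (default: the covariate-map flags plus demographics and the 90-day
#'   hospitalisation flag).
#' @param verbose print per-stage event counts to stderr.
#' @return list of class `vte_report` with `incidence`, `followup`,
#'   `cox_recurrence`, `logistic_hospitalisation`, `cohort`, `events`.
#' @export
run_analysis <- function(data, config = study_config(), out_dir = NULL,
                         risk_candidates = NULL, verbose = FALSE) {
  dataset <- if (inherits(data, "claims_dataset")) data else
    read_claims_dataset(file.path(data, "persons.csv"),
                        file.path(data, "claims.csv"),
                        file.path(data, "stays.csv"))
  say <- function(...) if (verbose) message("[vteclaims] ", ...)
  say("dataset: ", nrow(dataset$persons), " persons, ",
      nrow(dataset$claims), " claims, ", nrow(dataset$stays), " stays")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  hosp <- stage("find_hospital_events",
                find_hospital_events(dataset$stays, config$code_set))
  comm <- stage("find_community_dvt",
                find_community_dvt(dataset$claims, config$rule))
  say("hospital events: ", nrow(hosp), "; community DVT events: ", nrow(comm))
  adj <- stage("adjudicate_index_events",
               adjudicate_index_events(hosp, comm, dataset$persons, config))
  say("adjudicated events: ", nrow(adj$events), " (",
      sum(adj$events$in_window), " in window); cohort: ", nrow(adj$cohort))
  rec <- stage("detect_recurrences",
               detect_recurrences(adj$cohort, adj$events, config))
  cohort <- stage("extract_covariates",
                  extract_covariates(rec$cohort, dataset$claims,
                                     dataset$stays, config))
  incidence <- stage("estimate_incidence",
                     estimate_incidence(adj$events, dataset$persons, config))
  followup <- stage("followup_report",
                    followup_report(cohort, rec$recurrences, config))

  if (is.null(risk_candidates))
    risk_candidates <- c(names(config$covariates),
                         "prior_hospitalisation_90d", "age_ge_60",
                         "sex_female")
  cox <- logit <- NULL
  if (nrow(cohort) > 0L) {
    cox <- stage("cox_recurrence", tryCatch(
      two_step_procedure(cohort, model_spec("RECURRENCE_TIME_TO_EVENT",
                                            risk_candidates)),
      error = function(e) { say("Cox model: ", conditionMessage(e)); NULL }))
    logit <- stage("logistic_hospitalisation", tryCatch(
      two_step_procedure(cohort, model_spec("HOSPITAL_SETTING_BINARY",
                                            risk_candidates)),
      error = function(e) { say("logistic model: ", conditionMessage(e)); NULL }))
  }

  report <- structure(list(incidence = incidence, followup = followup,
                           cox_recurrence = cox,
                           logistic_hospitalisation = logit,
                           cohort = cohort, events = adj$events,
                           recurrences = rec$recurrences),
                      class = "vte_report")
  if (!is.null(out_dir)) write_report_bundle(report, config, out_dir)
  report
}

prop_rows <- function(props) {
  rows <- lapply(names(props), function(g) {
    p <- props[[g]]
    if (is.null(p)) return(NULL)
    data.frame(group = g, k = p$k, n = p$n, percent = p$percent,
               ci_low = p$ci_low, ci_high = p$ci_high)
  })
  do.call(rbind, rows)
}

write_report_bundle <- function(report, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    fwrite(as.data.frame(obj), p)
    files <<- c(files, p)
  }
  wr(report$incidence, "incidence.csv")
  fu <- report$followup
  if (!is.null(prop_rows(fu$recurrence$proportions)))
    wr(prop_rows(fu$recurrence$proportions), "recurrence.csv")
  if (!is.null(prop_rows(fu$mortality$proportions)))
    wr(prop_rows(fu$mortality$proportions), "mortality.csv")
  if (!is.null(fu$km_recurrence)) wr(fu$km_recurrence$at_months,
                                     "km_recurrence.csv")
  if (!is.null(fu$km_death)) wr(fu$km_death$at_months, "km_death.csv")
  if (!is.null(report$cox_recurrence) &&
      nrow(report$cox_recurrence$terms) > 0L)
    wr(report$cox_recurrence$terms, "cox_recurrence.csv")
  if (!is.null(report$logistic_hospitalisation) &&
      nrow(report$logistic_hospitalisation$terms) > 0L)
    wr(report$logistic_hospitalisation$terms, "logistic_hospitalisation.csv")

  json <- list(incidence = as.data.frame(report$incidence),
               followup = followup_report_json(fu),
               cox_recurrence = model_result_json(report$cox_recurrence),
               logistic_hospitalisation =
                 model_result_json(report$logistic_hospitalisation))
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  files <- c(files, jp)
  write_manifest(out_dir, files, config)
  invisible(files)
}

#' @export
print.vte_report <- function(x, ...) {
  cat("<vte_report>\n\nIncidence (annual, per 100 000):\n")
  print(as.data.frame(x$incidence), digits = 4)
  fu <- x$followup
  cat("\nCohort:", sum(fu$n_by_group), "patients (",
      paste(sprintf("%s %d", names(fu$n_by_group), fu$n_by_group),
            collapse = ", "), ")\n")
  if (!is.null(fu$recurrence$proportions$ALL)) {
    cat("12-month recurrence: ")
    print(fu$recurrence$proportions$ALL)
  }
  if (!is.null(fu$mortality$proportions$ALL)) {
    cat("12-month mortality:  ")
    print(fu$mortality$proportions$ALL)
  }
  invisible(x)
}

#' Validate an on-disk dataset
#'
#' Schema, date, enum and referential-integrity checks of the three CSV
#' tables; returns a pass/fail report rather than stopping at the first
#' problem.
#'
#' @param data_dir directory containing the three CSVs.
#' @return list with `ok` (logical) and `errors` (character).
#' @export
validate_claims_dir <- function(data_dir) {
  errors <- character(0)
  paths <- file.path(data_dir, c("persons.csv", "claims.csv", "stays.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    return(list(ok = FALSE, errors = paste("missing file:", missing)))
  ds <- tryCatch(read_claims_dataset(paths[1], paths[2], paths[3]),
                 error = function(e) {
                   errors <<- c(errors, conditionMessage(e))
                   NULL
                 })
  list(ok = is.null(ds) == FALSE && length(errors) == 0L, errors = errors,
       dataset = ds)
}
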
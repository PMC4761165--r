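## Study configuration: the observation window, age threshold, lookback and
## follow-up horizons, national reference population, the episode rule that
## parameterises case finding, and the covariate map used for the 12-month
## lookback flags.

#' Temporal rule parameters for case finding and adjudication
#'
#' All windows are whole days with inclusive endpoints.
#'
#' @param heparin_window_days half-width of the heparin/fondaparinux delivery
#'   window around the echo-Doppler date T0 (default 7, i.e. T0 +/- 7).
#' @param vka_window_days VKA delivery window after T0 (default 7).
#' @param migration_window_days a DVT followed by a PE within this many days
#'   is collapsed into that PE ("clot migration"; default 30).
#' @param comm_to_hosp_window_days a community DVT followed by a hospital DVT
#'   stay within this many days is reclassified as hospital-managed,
#'   keeping the earlier index date (default 30).
#' @param recurrence_gap_days blanking period: an event within this many days
#'   of the index is treated as same-episode care, not recurrence (default 30).
#' @return object of class `episode_rule`.
#' @export
episode_rule <- function(heparin_window_days = 7L,
                         vka_window_days = 7L,
                         migration_window_days = 30L,
                         comm_to_hosp_window_days = 30L,
                         recurrence_gap_days = 30L) {
  r <- list(heparin_window_days = as.integer(heparin_window_days),
            vka_window_days = as.integer(vka_window_days),
            migration_window_days = as.integer(migration_window_days),
            comm_to_hosp_window_days = as.integer(comm_to_hosp_window_days),
            recurrence_gap_days = as.integer(recurrence_gap_days))
  bad <- names(r)[vapply(r, function(v) is.na(v) || v <= 0L, logical(1))]
  if (length(bad) > 0L)
    stop("episode rule windows must be positive integers: ",
         paste(bad, collapse = ", "))
  structure(r, class = "episode_rule")
}

#' Study configuration
#'
#' @param study_start,study_end bounds of the event-ascertainment window
#'   (inclusive); default two calendar years, 2010-01-01 to 2011-12-31.
#' @param lookback_days covariate lookback before the index date (default 365).
#' @param followup_days outcome follow-up after the index date (default 365).
#' @param adult_age_min minimum age (completed years) at the event date for
#'   cohort inclusion (default 18).
#' @param national_population reference population for extrapolating event
#'   counts (default 65 026 885, France 2011).
#' @param code_set a [vte_code_set()].
#' @param rule an [episode_rule()].
#' @param covariates covariate map, see [default_covariate_map()].
#' @return object of class `study_config`.
#' @export
study_config <- function(study_start = as.Date("2010-01-01"),
                         study_end = as.Date("2011-12-31"),
                         lookback_days = 365L,
                         followup_days = 365L,
                         adult_age_min = 18L,
                         national_population = 65026885L,
                         code_set = vte_code_set(),
                         rule = episode_rule(),
                         covariates = default_covariate_map()) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (!(study_start < study_end)) stop("study_start must precede study_end")
  for (nm in c("lookback_days", "followup_days", "adult_age_min"))
    if (get(nm) <= 0) stop(nm, " must be positive")
  if (national_population <= 0) stop("national_population must be positive")
  if (rule$recurrence_gap_days >= followup_days)
    stop("recurrence_gap_days must be smaller than followup_days")
  structure(list(study_start = study_start, study_end = study_end,
                 lookback_days = as.integer(lookback_days),
                 followup_days = as.integer(followup_days),
                 adult_age_min = as.integer(adult_age_min),
                 national_population = as.integer(national_population),
                 code_set = code_set, rule = rule, covariates = covariates),
            class = "study_config")
}

#' Default covariate map for the 12-month lookback
#'
#' Each entry names a risk-factor flag and says how it is detected in the
#' lookback window: `stay` = a hospital stay carrying one of the listed
#' ICD-10 codes (primary or associated), `claim` = a community claim of the
#' given service class, `any_stay` = any hospital stay overlapping the
#' window. The stay-code lists here are compact synthetic defaults (one to
#' three representative codes per condition); real-data users supply their
#' own lists via the config file.
#'
#' @return named list of covariate definitions.
#' @export
default_covariate_map <- function() {
  list(
    prior_hospitalisation = list(kind = "any_stay"),
    surgery        = list(kind = "stay", codes = c("Z98.8")),
    trauma         = list(kind = "stay", codes = c("T14.9", "S42.2")),
    hip_fracture   = list(kind = "stay", codes = c("S72.0")),
    cancer         = list(kind = "stay", codes = c("C18.9", "C34.9", "C50.9")),
    obesity        = list(kind = "stay", codes = c("E66.0", "E66.9")),
    pregnancy      = list(kind = "stay", codes = c("O80")),
    heart_failure  = list(kind = "stay", codes = c("I50.0", "I50.9")),
    renal_disease  = list(kind = "stay", codes = c("N17.9", "N18.9")),
    gi_haemorrhage = list(kind = "stay", codes = c("K92.2")),
    hormonal_therapy = list(kind = "claim", class = "HORMONAL_THERAPY")
  )
}

#' Load a study configuration from a YAML/JSON file
#'
#' Recognised top-level keys mirror the arguments of [study_config()]
#' (dates as ISO strings); `rule:` holds [episode_rule()] fields,
#' `code_set:` holds `dvt_codes`/`pe_codes` lists, `covariates:` a covariate
#' map. Missing keys fall back to the defaults.
#'
#' @param path YAML or JSON file, or `NULL` for all defaults.
#' @return a `study_config`.
#' @export
load_study_config <- function(path = NULL) {
  if (is.null(path)) return(study_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("study_start", "study_end"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- as.Date(cfg[[nm]])
  for (nm in c("lookback_days", "followup_days", "adult_age_min",
               "national_population"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$rule)) args$rule <- do.call(episode_rule, cfg$rule)
  if (!is.null(cfg$code_set)) {
    cs <- list()
    if (!is.null(cfg$code_set$dvt_codes)) cs$dvt_codes <- unlist(cfg$code_set$dvt_codes)
    if (!is.null(cfg$code_set$pe_codes))  cs$pe_codes  <- unlist(cfg$code_set$pe_codes)
    args$code_set <- do.call(vte_code_set, cs)
  }
  if (!is.null(cfg$covariates)) args$covariates <- cfg$covariates
  do.call(study_config, args)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  window:", format(x$study_start), "to", format(x$study_end), "\n")
  cat("  lookback/followup:", x$lookback_days, "/", x$followup_days, "days\n")
  cat("  adult age >=", x$adult_age_min,
      "; national population", format(x$national_population, big.mark = " "), "\n")
  invisible(x)
}
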
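## Annual incidence per 100 000 with 95% CI and national extrapolation.
##
## The CI treats the annualised event count as Poisson: half-width
## 1.96 * sqrt(events / years), scaled to the per-100 000 rate. Category
## rows (PE, hospital DVT, community DVT) are summed into all-DVT and
## all-VTE totals; additivity is exact for counts and extrapolated events
## and holds for rates because all categories share denominator and years.

INCIDENCE_CATEGORIES <- c("PE", "DVT_HOSP", "DVT_COMM")

#' Annualised incidence per 100 000 with a 95% confidence interval
#'
#' @param event_count events observed over the study window (may exceed the
#'   number of patients: one patient can contribute several events).
#' @param denominator population at risk (adult mid-study population).
#' @param years length of the observation window in years.
#' @param category optional category label.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data.frame of class `incidence_estimate`: `category`,
#'   `events`, `denominator`, `years`, `rate`, `ci_low`, `ci_high`,
#'   `extrapolated` (NA until [extrapolate_incidence()]).
#' @examples
#' compute_incidence(675, 525430, 2)  # rate close to 64.2 per 100 000
#' @export
compute_incidence <- function(event_count, denominator, years,
                              category = NA_character_, conf_level = 0.95) {
  if (event_count < 0) stop("event_count must be non-negative")
  if (denominator <= 0) stop("denominator must be positive")
  if (years <= 0) stop("years must be positive")
  z <- qnorm(1 - (1 - conf_level) / 2)
  rate <- (event_count / years) / denominator * 1e5
  half <- z * sqrt(event_count / years) / denominator * 1e5
  out <- data.frame(category = category, events = as.integer(event_count),
                    denominator = denominator, years = years, rate = rate,
                    ci_low = max(0, rate - half), ci_high = rate + half,
                    extrapolated = NA_integer_)
  class(out) <- c("incidence_estimate", class(out))
  out
}

#' Extrapolate an incidence estimate to a national population
#'
#' Multiplies the unrounded annual rate by the national population and
#' rounds last.
#'
#' @param estimate an `incidence_estimate` (or data.frame with a `rate`
#'   column).
#' @param national_population reference population size.
#' @return the estimate with `extrapolated` filled in (integer events).
#' @export
extrapolate_incidence <- function(estimate, national_population) {
  stopifnot(national_population >= 0)
  estimate$extrapolated <- as.integer(round(estimate$rate *
                                              national_population / 1e5))
  estimate
}

#' Summarise per-category incidence into a full incidence table
#'
#' Takes per-category rows (must include `PE`, `DVT_HOSP` and `DVT_COMM`)
#' and appends `DVT_ALL` and `VTE_ALL` rows by summation of event counts,
#' rates and extrapolated counts. Confidence intervals of the totals are
#' recomputed from the summed counts when denominator and years are
#' available and shared.
#'
#' @param estimates data.frame of per-category rows (rbind of
#'   `incidence_estimate`s, or any data.frame with columns `category`,
#'   `events`, `rate`, and optionally `ci_low`/`ci_high`, `denominator`,
#'   `years`, `extrapolated`).
#' @return data.frame with the five category rows, class `incidence_table`.
#' @export
summarize_incidence <- function(estimates) {
  est <- as.data.frame(estimates)
  if (!all(c("category", "events", "rate") %in% names(est)))
    stop("estimates need columns category, events, rate")
  missing_cat <- setdiff(INCIDENCE_CATEGORIES, est$category)
  if (length(missing_cat) > 0L)
    stop("missing incidence category: ", paste(missing_cat, collapse = ", "))
  for (col in c("ci_low", "ci_high", "denominator", "years", "extrapolated"))
    if (!col %in% names(est)) est[[col]] <- NA_real_
  est <- est[match(INCIDENCE_CATEGORIES, est$category),
             c("category", "events", "denominator", "years", "rate",
               "ci_low", "ci_high", "extrapolated")]

  total_row <- function(rows, label) {
    denom <- unique(rows$denominator)
    yrs <- unique(rows$years)
    shared <- length(denom) == 1L && length(yrs) == 1L &&
      !is.na(denom) && !is.na(yrs)
    events <- sum(rows$events)
    if (shared) {
      tot <- compute_incidence(events, denom, yrs, category = label)
      tot$rate <- sum(rows$rate)   # additivity holds exactly; avoids drift
                                   # when inputs carry externally rounded rates
      half <- qnorm(0.975) * sqrt(events / yrs) / denom * 1e5
      tot$ci_low <- max(0, tot$rate - half); tot$ci_high <- tot$rate + half
    } else {
      tot <- data.frame(category = label, events = events,
                        denominator = denom[1], years = yrs[1],
                        rate = sum(rows$rate), ci_low = NA_real_,
                        ci_high = NA_real_, extrapolated = NA_integer_)
    }
    tot$extrapolated <- if (all(!is.na(rows$extrapolated)))
      as.integer(sum(rows$extrapolated)) else NA_integer_
    tot
  }
  dvt <- total_row(est[est$category %in% c("DVT_HOSP", "DVT_COMM"), ],
                   "DVT_ALL")
  vte <- total_row(est, "VTE_ALL")
  out <- rbind(est, dvt, vte)
  rownames(out) <- NULL
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Estimate incidence from adjudicated events
#'
#' Counts in-window adjudicated events per category, uses the adult
#' mid-study population as denominator, and extrapolates to the national
#' population.
#'
#' @param events adjudicated event table ([adjudicate_index_events()]).
#' @param persons validated persons table.
#' @param config a [study_config()].
#' @return an `incidence_table`.
#' @export
estimate_incidence <- function(events, persons, config = study_config()) {
  events <- as.data.table(events); persons <- as.data.table(persons)
  midpoint <- config$study_start +
    floor(as.integer(config$study_end - config$study_start) / 2)
  covered <- persons[coverage_start <= midpoint & coverage_end >= midpoint &
                       birth_date <= midpoint]
  denom <- sum(age_at(covered$birth_date, midpoint) >= config$adult_age_min)
  yrs <- window_years(config)
  inw <- events[in_window == TRUE]
  rows <- do.call(rbind, lapply(INCIDENCE_CATEGORIES, function(cat)
    extrapolate_incidence(
      compute_incidence(sum(inw$category == cat), denom, yrs, category = cat),
      config$national_population)))
  summarize_incidence(rows)
}
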
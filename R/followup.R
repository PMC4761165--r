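## Twelve-month follow-up statistics: proportions with Wald CIs,
## chi-square and Fisher exact tests on outcome-by-setting contingency
## tables, and Kaplan-Meier cumulative incidence of recurrence and death.

#' Proportion with a 95% Wald confidence interval, in percent
#'
#' @param k numerator; @param n denominator (> 0); @param conf_level
#'   confidence level.
#' @return list of class `proportion_estimate`: `k`, `n`, `percent`,
#'   `ci_low`, `ci_high` (percent, clamped to `[0, 100]`).
#' @examples
#' proportion_with_ci(99, 1804)  # 5.5% of patients with a recurrence
#' @export
proportion_with_ci <- function(k, n, conf_level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  structure(list(k = as.integer(k), n = as.integer(n), percent = 100 * p,
                 ci_low = max(0, 100 * (p - half)),
                 ci_high = min(100, 100 * (p + half))),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% [95%% CI %.1f-%.1f]\n", x$k, x$n, x$percent,
              x$ci_low, x$ci_high))
  invisible(x)
}

check_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency table must hold non-negative integer counts")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  counts
}

#' Pearson chi-square test of homogeneity
#'
#' Classical statistic sum((O - E)^2 / E) without continuity correction;
#' degrees of freedom (r - 1)(c - 1).
#'
#' @param counts r x c matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(counts) {
  counts <- check_table(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-square test undefined with a zero row/column margin")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Fisher's exact test for an r x c table
#'
#' Two-sided p by the standard r x c convention: the sum of probabilities,
#' under the hypergeometric distribution with the observed margins, of all
#' tables no more probable than the observed one. Exact enumeration only;
#' tables with total count above `max_total` are refused.
#'
#' @param counts r x c matrix of counts.
#' @param max_total guard on the table total for exact mode (default 500).
#' @return the exact p-value.
#' @export
fisher_exact_rxc <- function(counts, max_total = 500L) {
  counts <- check_table(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    return(1)  # degenerate margins: only one table is possible
  if (sum(counts) > max_total)
    stop("table total ", sum(counts), " exceeds the exact-mode guard (",
         max_total, "); a Monte-Carlo mode is out of scope")
  unname(fisher.test(counts, workspace = 2e7)$p.value)
}

#' Kaplan-Meier cumulative incidence curve
#'
#' Product-limit estimator with Greenwood variance; cumulative incidence is
#' 1 - S(t). Event and censoring are mutually exclusive per subject
#' (`event = 1` event, `0` censored).
#'
#' @param durations days from index to event/censoring (>= 0).
#' @param event integer/logical event indicator.
#' @param conf_level confidence level for the Greenwood ("plain") interval.
#' @return object of class `km_curve`: data.frame with `time`, `n_risk`,
#'   `n_event`, `survival`, `cuminc`, `ci_low`, `ci_high` (on the
#'   cumulative-incidence scale), plus the underlying `survfit` object as
#'   attribute `fit`.
#' @export
km_estimate <- function(durations, event, conf_level = 0.95) {
  if (any(durations < 0)) stop("negative duration")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(durations, event) ~ 1,
                           conf.type = "plain", conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  lo <- ifelse(is.na(s$lower), pmax(0, s$surv - 0), s$lower)
  hi <- ifelse(is.na(s$upper), s$surv, s$upper)
  out <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    survival = s$surv, cuminc = 1 - s$surv,
                    ci_low = pmax(0, 1 - hi), ci_high = pmin(1, 1 - lo))
  attr(out, "fit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function evaluation: the estimate at the largest event time not
#' exceeding each requested time (cumulative incidence 0 before the first
#' event).
#'
#' @param curve a `km_curve`; @param times numeric vector of days.
#' @return data.frame with `time`, `cuminc`, `ci_low`, `ci_high`.
#' @export
km_at <- function(curve, times) {
  idx <- findInterval(times, curve$time)
  pick <- function(col, default) ifelse(idx == 0L, default, col[pmax(idx, 1L)])
  data.frame(time = times,
             cuminc = pick(curve$cuminc, 0),
             ci_low = pick(curve$ci_low, 0),
             ci_high = pick(curve$ci_high, 0))
}

km_month_marks <- function() c(30L, 91L, 182L, 273L, 365L)

group_km <- function(cohort, time_col, status_col, marks) {
  curves <- list(ALL = km_estimate(cohort[[time_col]], cohort[[status_col]]))
  for (g in INCIDENCE_CATEGORIES) {
    sub <- cohort[cohort$index_category == g, ]
    if (nrow(sub) > 0L && any(!is.na(sub[[time_col]])))
      curves[[g]] <- km_estimate(sub[[time_col]], sub[[status_col]])
  }
  marks_tab <- do.call(rbind, lapply(names(curves), function(g) {
    cbind(group = g, km_at(curves[[g]], marks))
  }))
  list(curves = curves, at_months = marks_tab)
}

#' Twelve-month recurrence and mortality report
#'
#' Produces, by index category (PE, hospital DVT, community DVT) and
#' overall: the at-least-one-recurrence table with a chi-square p-value,
#' the recurrence-frequency distribution, the type-of-recurrence
#' cross-table with a Fisher exact p-value, mortality proportions with
#' Wald CIs (plus the hospital-vs-community DVT chi-square), and
#' Kaplan-Meier cumulative incidence of first recurrence (deaths censor)
#' and of death, evaluated at months 1, 3, 6, 9, 12 (days 30, 91, 182,
#' 273, 365).
#'
#' @param cohort cohort with recurrence fields ([detect_recurrences()]).
#' @param recurrences the per-event recurrence table.
#' @param config a [study_config()].
#' @return list of class `followup_report`.
#' @export
followup_report <- function(cohort, recurrences, config = study_config()) {
  cohort <- as.data.table(cohort)
  recurrences <- as.data.table(recurrences)
  groups <- INCIDENCE_CATEGORIES
  n_by <- vapply(groups, function(g) sum(cohort$index_category == g),
                 integer(1))
  notices <- character(0)

  ## at least one recurrence
  k_by <- vapply(groups, function(g)
    sum(cohort$index_category == g & cohort$n_recurrences > 0L), integer(1))
  rec_tab <- rbind(yes = k_by, no = n_by - k_by)
  rec_props <- lapply(seq_along(groups), function(i)
    if (n_by[[i]] > 0L) proportion_with_ci(k_by[[i]], n_by[[i]]) else NULL)
  names(rec_props) <- groups
  rec_props$ALL <- if (nrow(cohort) > 0L)
    proportion_with_ci(sum(k_by), nrow(cohort)) else NULL
  rec_test <- if (all(n_by > 0L) && sum(k_by) > 0L)
    pearson_chi2(rec_tab[, n_by > 0L, drop = FALSE]) else {
      notices <- c(notices, "recurrence chi-square skipped (empty group or no recurrences)")
      NULL
    }

  ## frequency of recurrence among patients with >= 1
  freq_levels <- c("1", "2", "3+")
  freq_tab <- vapply(groups, function(g) {
    nr <- cohort[index_category == g & n_recurrences > 0L]$n_recurrences
    c(sum(nr == 1L), sum(nr == 2L), sum(nr >= 3L))
  }, integer(3))
  rownames(freq_tab) <- freq_levels

  ## type of recurrence (all recurrent events) by index category
  type_tab <- NULL; type_test <- NULL
  if (nrow(recurrences) > 0L) {
    rec2 <- merge(recurrences,
                  cohort[, .(person_id, index_category)], by = "person_id")
    type_tab <- table(factor(rec2$recurrence_category, levels = groups),
                      factor(rec2$index_category, levels = groups))
    type_tab <- unclass(type_tab)
    keep_cols <- colSums(type_tab) > 0L
    keep_rows <- rowSums(type_tab) > 0L
    if (sum(keep_cols) >= 2L && sum(keep_rows) >= 2L) {
      type_test <- tryCatch(
        fisher_exact_rxc(type_tab[keep_rows, keep_cols, drop = FALSE]),
        error = function(e) {
          notices <<- c(notices, paste("Fisher test skipped:",
                                       conditionMessage(e)))
          NULL
        })
    }
  } else notices <- c(notices, "no recurrences: type-of-recurrence table empty")

  ## all-cause mortality within follow-up
  cohort[, dead_by_followup := !is.na(death_date) &
           death_date <= index_date + config$followup_days]
  d_by <- vapply(groups, function(g)
    sum(cohort$index_category == g & cohort$dead_by_followup), integer(1))
  mort_props <- lapply(seq_along(groups), function(i)
    if (n_by[[i]] > 0L) proportion_with_ci(d_by[[i]], n_by[[i]]) else NULL)
  names(mort_props) <- groups
  mort_props$ALL <- if (nrow(cohort) > 0L)
    proportion_with_ci(sum(d_by), nrow(cohort)) else NULL
  mort_dvt_test <- if (all(n_by[c("DVT_HOSP", "DVT_COMM")] > 0L) &&
                       sum(d_by[c("DVT_HOSP", "DVT_COMM")]) > 0L)
    pearson_chi2(rbind(dead = d_by[c("DVT_HOSP", "DVT_COMM")],
                       alive = (n_by - d_by)[c("DVT_HOSP", "DVT_COMM")]))
  else NULL

  ## KM curves
  km_rec <- NULL; km_death <- NULL
  if (nrow(cohort) > 0L) {
    km_rec <- group_km(cohort, "time_to_event", "event_status",
                       km_month_marks())
    cohort[, `:=`(death_time = fifelse(dead_by_followup,
                                       as.integer(death_date - index_date),
                                       as.integer(pmin(censor_date,
                                                       index_date +
                                                         config$followup_days) -
                                                    index_date)),
                  death_status = as.integer(dead_by_followup))]
    km_death <- group_km(cohort, "death_time", "death_status",
                         km_month_marks())
  }

  structure(list(
    n_by_group = n_by,
    recurrence = list(table = rec_tab, proportions = rec_props,
                      chi2 = rec_test),
    recurrence_frequency = freq_tab,
    recurrence_type = list(table = type_tab, fisher_p = type_test),
    mortality = list(deaths = d_by, proportions = mort_props,
                     dvt_setting_chi2 = mort_dvt_test),
    km_recurrence = km_rec, km_death = km_death,
    notices = notices), class = "followup_report")
}
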
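## Case finding and adjudication.
##
## Hospital VTE events are captured from ICD-10 codes on stays (primary or
## associated diagnosis). Community DVT has no diagnosis code, so it is
## identified by a three-criterion temporal algorithm on reimbursement
## claims: an echo-Doppler exam at T0, a heparin (LMWH or fondaparinux)
## delivery within the heparin window, and a subsequent VKA delivery within
## the VKA window, in that order (same-day ties allowed). Adjudication then
## applies the clot-migration rule (a DVT evolving into a PE counts as that
## index PE only) and the setting rule (a community DVT followed shortly by
## a hospital DVT stay is hospital-managed, keeping the earlier index date).

EVENT_PRIORITY <- c(PE = 1L, DVT_HOSP = 2L, DVT_COMM = 3L)

event_category <- function(vte_type, setting)
  ifelse(vte_type == "PE", "PE",
         ifelse(setting == "HOSPITAL", "DVT_HOSP", "DVT_COMM"))

empty_events <- function() {
  data.table(person_id = character(), event_date = as.Date(character()),
             vte_type = character(), setting = character(),
             source_kind = character())
}

empty_cohort <- function() {
  data.table(person_id = character(), index_date = as.Date(character()),
             index_category = character(), age_at_index = integer(),
             sex = character(), death_date = as.Date(character()),
             censor_date = as.Date(character()))
}

#' Capture VTE events from hospital stays
#'
#' One event per qualifying stay, dated at admission. A stay whose codes
#' match both the PE and the DVT set yields a single PE event (consistent
#' with the clot-migration precedence). The source records whether the
#' qualifying code was the primary or an associated diagnosis.
#'
#' @param stays validated stays table.
#' @param code_set a [vte_code_set()].
#' @return data.table of events (`vte_type` PE/DVT, `setting` HOSPITAL).
#' @export
find_hospital_events <- function(stays, code_set = vte_code_set()) {
  stays <- as.data.table(stays)
  if (nrow(stays) == 0L) return(empty_events())
  pe <- stay_matches(stays, code_set$pe_codes)
  dvt <- stay_matches(stays, code_set$dvt_codes)
  is_pe <- pe$primary | pe$associated
  is_dvt <- !is_pe & (dvt$primary | dvt$associated)
  hit <- is_pe | is_dvt
  if (!any(hit)) return(empty_events())
  out <- data.table(
    person_id = stays$person_id[hit],
    event_date = stays$admission_date[hit],
    vte_type = ifelse(is_pe[hit], "PE", "DVT"),
    setting = "HOSPITAL",
    source_kind = ifelse(is_pe[hit],
                         ifelse(pe$primary[hit], "PRIMARY_DX", "ASSOCIATED_DX"),
                         ifelse(dvt$primary[hit], "PRIMARY_DX",
                                "ASSOCIATED_DX")))
  setorder(out, person_id, event_date)
  out[]
}

#' Identify community-treated DVT from the claim triplet
#'
#' For each echo-Doppler claim at T0 that is not already inside a detected
#' episode, a community DVT is emitted (index date T0) iff there is a
#' heparin/fondaparinux delivery within `heparin_window_days` of T0 and a
#' VKA delivery within `vka_window_days` after T0, with dates ordered
#' echo <= heparin <= VKA (same-day ties allowed). Once an episode is
#' detected, further echo claims within `vka_window_days` of its index are
#' treated as part of the same episode and skipped.
#'
#' @param claims validated claims table.
#' @param rule an [episode_rule()].
#' @return data.table of community DVT events.
#' @export
find_community_dvt <- function(claims, rule = episode_rule()) {
  claims <- as.data.table(claims)
  if (nrow(claims) == 0L) return(empty_events())
  echo <- claims[service_class == "ECHO_DOPPLER",
                 .(person_id, t0 = service_date)]
  hep <- claims[service_class %in% c("LMWH", "FONDAPARINUX"),
                .(person_id, hdate = service_date)]
  vka <- claims[service_class == "VKA", .(person_id, vdate = service_date)]
  if (nrow(echo) == 0L || nrow(hep) == 0L || nrow(vka) == 0L)
    return(empty_events())
  setorder(echo, person_id, t0)

  hw <- rule$heparin_window_days; vw <- rule$vka_window_days
  ## ordering (echo <= heparin) restricts the heparin window to [T0, T0+hw];
  ## the earliest such heparin is the least constraining partner for the VKA
  echo[, idx := .I]
  echo[, `:=`(lo = t0, hi = t0 + hw)]
  h1 <- hep[echo, on = .(person_id, hdate >= lo, hdate <= hi),
            .(idx = i.idx, h = x.hdate)]
  h1 <- h1[!is.na(h)]
  h1 <- if (nrow(h1) > 0L) h1[, .(hmin = min(h)), by = idx] else
    data.table(idx = integer(), hmin = as.Date(character()))
  echo[, hmin := as.Date(NA)]
  echo[h1, hmin := i.hmin, on = "idx"]
  echo[, vhi := t0 + vw]
  cand <- echo[!is.na(hmin)]
  if (nrow(cand) > 0L) {
    v1 <- vka[cand, on = .(person_id, vdate >= hmin, vdate <= vhi),
              .(idx = i.idx, v = x.vdate)]
    ok_idx <- unique(v1[!is.na(v)]$idx)
  } else ok_idx <- integer(0)
  echo[, keep := idx %in% ok_idx]

  qual <- echo[keep == TRUE]
  if (nrow(qual) == 0L) return(empty_events())
  ## greedy per-person scan: skip qualifying echoes inside the episode span
  ## of the previously detected one
  span <- vw
  picked <- qual[, {
    sel <- logical(.N)
    last <- as.Date("0001-01-01")
    for (i in seq_len(.N)) {
      if (t0[i] > last) { sel[i] <- TRUE; last <- t0[i] + span }
    }
    .(t0 = t0[sel])
  }, by = person_id]
  out <- data.table(person_id = picked$person_id, event_date = picked$t0,
                    vte_type = "DVT", setting = "COMMUNITY",
                    source_kind = "ALGORITHM")
  setorder(out, person_id, event_date)
  out[]
}

adjudicate_person <- function(date, category, rule) {
  ## inputs sorted by (date, priority); returns keep mask and, for events
  ## kept, the possibly reclassified category
  n <- length(date)
  keep <- rep(TRUE, n)
  cat2 <- category
  ## (b) clot migration: a DVT followed by a PE within the window collapses
  ## into that PE
  pe_dates <- date[category == "PE"]
  if (length(pe_dates) > 0L) {
    for (i in which(category != "PE")) {
      if (any(pe_dates >= date[i] &
              pe_dates <= date[i] + rule$migration_window_days))
        keep[i] <- FALSE
    }
  }
  ## (c) community DVT followed by a hospital DVT stay: one hospital-managed
  ## event keeping the earlier (community) index date
  for (i in which(keep & cat2 == "DVT_COMM")) {
    j <- which(keep & cat2 == "DVT_HOSP" & date >= date[i] &
                 date <= date[i] + rule$comm_to_hosp_window_days)
    if (length(j) > 0L) {
      keep[j[1L]] <- FALSE
      cat2[i] <- "DVT_HOSP"
    }
  }
  ## same-day ties: the sort puts PE > hospital DVT > community DVT first
  for (d in unique(date[keep])) {
    k <- which(keep & date == d)
    if (length(k) > 1L) keep[k[-1L]] <- FALSE
  }
  list(keep = keep, category = cat2)
}

#' Adjudicate index events and build the analysis cohort
#'
#' Combines hospital and community events, drops events of persons below
#' the adult age threshold at the event date and events after death,
#' applies the clot-migration rule, then the community-to-hospital
#' reclassification, and resolves same-day ties as PE > hospital DVT >
#' community DVT. The event table keeps every adjudicated event (one
#' person can contribute more than one); the cohort takes each person's
#' first adjudicated event inside the study window as the index.
#'
#' @param hospital_events,community_events outputs of the two finders.
#' @param persons validated persons table.
#' @param config a [study_config()].
#' @return list with `events` (all adjudicated events, logical `in_window`)
#'   and `cohort` (one row per person: index date/category, age, death and
#'   censor dates).
#' @export
adjudicate_index_events <- function(hospital_events, community_events,
                                    persons, config = study_config()) {
  rule <- config$rule
  ev <- rbind(as.data.table(hospital_events), as.data.table(community_events),
              fill = TRUE)
  persons <- as.data.table(persons)
  cohort_cols <- c("person_id", "index_date", "index_category",
                   "age_at_index", "sex", "death_date", "censor_date")
  empty_out <- function() {
    list(events = cbind(empty_events(), category = character(0),
                        in_window = logical(0)),
         cohort = empty_cohort())
  }
  if (nrow(ev) == 0L) return(empty_out())
  ev <- merge(ev, persons[, .(person_id, sex, birth_date, death_date)],
              by = "person_id")
  ev <- ev[age_at(birth_date, event_date) >= config$adult_age_min]
  ev <- ev[is.na(death_date) | event_date <= death_date]
  if (nrow(ev) == 0L) return(empty_out())
  if (nrow(ev) > 0L) {
    ev[, category := event_category(vte_type, setting)]
    ev[, priority := EVENT_PRIORITY[category]]
    setorder(ev, person_id, event_date, priority)
    ev <- ev[, {
      r <- adjudicate_person(event_date, category, rule)
      out <- .SD[r$keep]
      out$category <- r$category[r$keep]
      out
    }, by = person_id]
    ev[, setting := ifelse(category == "DVT_COMM", "COMMUNITY", "HOSPITAL")]
    ev[, vte_type := ifelse(category == "PE", "PE", "DVT")]
    ev[, priority := NULL]
  }
  ev[, in_window := event_date >= config$study_start &
       event_date <= config$study_end]

  idx <- ev[in_window == TRUE]
  idx[, priority := EVENT_PRIORITY[category]]
  setorder(idx, person_id, event_date, priority)
  cohort <- idx[, .SD[1L], by = person_id,
                .SDcols = c("event_date", "category", "sex", "birth_date",
                            "death_date")]
  setnames(cohort, c("event_date", "category"),
           c("index_date", "index_category"))
  cohort[, age_at_index := age_at(birth_date, index_date)]
  cohort <- merge(cohort,
                  persons[, .(person_id, coverage_end)], by = "person_id")
  cohort[, censor_date := pmin(index_date + config$followup_days,
                               coverage_end,
                               fifelse(is.na(death_date),
                                       as.Date("9999-12-31"), death_date))]
  cohort[, `:=`(birth_date = NULL, coverage_end = NULL)]
  setcolorder(cohort, cohort_cols)
  list(events = ev[], cohort = cohort[])
}

#' Detect 12-month recurrences
#'
#' A recurrence is an adjudicated event strictly later than the index date
#' plus the blanking gap and no later than the end of follow-up or the
#' death date. Each is classified by category (PE / hospital DVT /
#' community DVT).
#'
#' @param cohort,events output of [adjudicate_index_events()] (events need
#'   not be restricted to the study window: follow-up may extend past it).
#' @param config a [study_config()] (its `rule` supplies the gap).
#' @return list: `cohort` augmented with `n_recurrences`,
#'   `first_recurrence_date`, `first_recurrence_category`, `time_to_event`
#'   and `event_status` (recurrence KM inputs; deaths censor), and
#'   `recurrences` (one row per recurrent event).
#' @export
detect_recurrences <- function(cohort, events, config = study_config()) {
  cohort <- as.data.table(cohort); events <- as.data.table(events)
  gap <- config$rule$recurrence_gap_days
  fu <- config$followup_days
  if (nrow(cohort) == 0L) {
    cohort[, `:=`(n_recurrences = integer(),
                  first_recurrence_date = as.Date(character()),
                  first_recurrence_category = character(),
                  event_status = integer(), time_to_event = integer())]
    return(list(cohort = cohort,
                recurrences = data.table(person_id = character(),
                                         recurrence_date = as.Date(character()),
                                         recurrence_category = character())))
  }
  rec <- events[cohort[, .(person_id, index_date, death_date)],
                on = "person_id", allow.cartesian = TRUE]
  rec <- rec[event_date > index_date + gap & event_date <= index_date + fu]
  rec <- rec[is.na(death_date) | event_date <= death_date]
  recurrences <- rec[, .(person_id, recurrence_date = event_date,
                         recurrence_category = category)]
  setorder(recurrences, person_id, recurrence_date)

  agg <- recurrences[, .(n_recurrences = .N,
                         first_recurrence_date = recurrence_date[1L],
                         first_recurrence_category = recurrence_category[1L]),
                     by = person_id]
  cohort <- merge(cohort, agg, by = "person_id", all.x = TRUE)
  cohort[is.na(n_recurrences), n_recurrences := 0L]
  ## product-limit inputs: event = first recurrence; death and end of
  ## follow-up censor
  cohort[, event_status := as.integer(n_recurrences > 0L)]
  cohort[, time_to_event := fifelse(
    event_status == 1L,
    as.integer(first_recurrence_date - index_date),
    as.integer(pmin(censor_date, index_date + fu) - index_date))]
  list(cohort = cohort[], recurrences = recurrences[])
}

#' Extract lookback covariate flags
#'
#' Each flag in the covariate map is TRUE iff a matching stay/claim occurs
#' in the window `[index - lookback_days, index)`. `prior_hospitalisation`
#' (kind `any_stay`) is TRUE iff any stay overlaps the window; a 90-day
#' variant `prior_hospitalisation_90d` is always added (the two lookback
#' horizons used for the hospitalisation history covariate). Demographic
#' flags `age_ge_60` and `sex_female` are added too.
#'
#' @param cohort cohort table with `index_date`.
#' @param claims,stays validated claim/stay tables.
#' @param config a [study_config()] carrying the covariate map.
#' @return the cohort with one logical column per flag.
#' @export
extract_covariates <- function(cohort, claims, stays,
                               config = study_config()) {
  cohort <- as.data.table(copy(cohort))
  claims <- as.data.table(claims); stays <- as.data.table(stays)
  if (nrow(cohort) == 0L) return(cohort)
  lb <- config$lookback_days
  win <- cohort[, .(person_id, wstart = index_date - lb, wend = index_date)]

  flag_stay_overlap <- function(days) {
    w <- cohort[, .(person_id, ws = index_date - days, we = index_date)]
    hit <- stays[w, on = .(person_id, admission_date < we,
                           discharge_date >= ws), nomatch = NULL,
                 .(person_id = person_id)]
    cohort$person_id %in% unique(hit$person_id)
  }
  flag_stay_codes <- function(codes) {
    m <- stay_matches(stays, codes)
    s <- stays[m$primary | m$associated]
    hit <- s[win, on = .(person_id, admission_date >= wstart,
                         admission_date < wend), nomatch = NULL,
             .(person_id = person_id)]
    cohort$person_id %in% unique(hit$person_id)
  }
  flag_claim_class <- function(class) {
    c2 <- claims[service_class == class]
    hit <- c2[win, on = .(person_id, service_date >= wstart,
                          service_date < wend), nomatch = NULL,
              .(person_id = person_id)]
    cohort$person_id %in% unique(hit$person_id)
  }

  for (nm in names(config$covariates)) {
    def <- config$covariates[[nm]]
    if (is.null(def$kind))
      stop("covariate '", nm, "' has no 'kind'")
    cohort[[nm]] <- switch(def$kind,
      any_stay = flag_stay_overlap(lb),
      stay = flag_stay_codes(expand_icd10_ranges(unlist(def$codes))),
      claim = flag_claim_class(def$class),
      stop("unknown covariate kind '", def$kind, "' for flag '", nm, "'"))
  }
  cohort$prior_hospitalisation_90d <- flag_stay_overlap(90L)
  cohort$age_ge_60 <- cohort$age_at_index >= 60L
  cohort$sex_female <- cohort$sex == "F"
  cohort[]
}

#' Run the full case-finding stage on a dataset
#'
#' Convenience wrapper: hospital capture, community algorithm,
#' adjudication, recurrence detection and covariate extraction.
#'
#' @param dataset a `claims_dataset`.
#' @param config a [study_config()].
#' @return list with `events`, `cohort` (with recurrence fields and
#'   covariate flags) and `recurrences`.
#' @export
build_cohort <- function(dataset, config = study_config()) {
  stopifnot(inherits(dataset, "claims_dataset"))
  hosp <- find_hospital_events(dataset$stays, config$code_set)
  comm <- find_community_dvt(dataset$claims, config$rule)
  adj <- adjudicate_index_events(hosp, comm, dataset$persons, config)
  rec <- detect_recurrences(adj$cohort, adj$events, config)
  cohort <- extract_covariates(rec$cohort, dataset$claims, dataset$stays,
                               config)
  list(events = adj$events, cohort = cohort, recurrences = rec$recurrences)
}
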
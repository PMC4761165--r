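## Synthetic claims generator.
##
## Emulates the structure of a national insurance claims sample: per-event
## community reimbursement rows with no diagnosis attached, DRG-coded
## hospital stays carrying ICD-10 primary/associated diagnoses, and death
## dates without cause. Category incidences, recurrence and death
## probabilities default to the published French 2010-2011 estimates so the
## pipeline can be exercised under realistic event frequencies, with the
## ground truth retained for sensitivity/specificity checks.

EVENT_CATEGORIES <- c("PE", "DVT_HOSP", "DVT_COMM")

default_recurrence_type_probs <- function() {
  m <- rbind(PE       = c(0.809, 0.191, 0.000),
             DVT_HOSP = c(0.143, 0.857, 0.000),
             DVT_COMM = c(0.375, 0.250, 0.375))
  colnames(m) <- EVENT_CATEGORIES
  m
}

#' Simulation parameters for the synthetic claims generator
#'
#' Annual first-event rates are per 100 000 adult person-years; recurrence
#' and death probabilities are 12-month probabilities conditional on the
#' index category. Defaults reproduce the published category incidences
#' (64.2 / 64.0 / 55.8 per 100 000 for PE, hospital DVT, community DVT),
#' recurrence proportions (7.6 / 4.4 / 4.4 %) and mortality (7.7 / 9.3 /
#' 0.9 %).
#'
#' @param n_persons number of persons to simulate.
#' @param seed integer; all randomness flows from it (stage k uses
#'   `seed + k`), so equal seeds give byte-identical datasets.
#' @param annual_rate_pe,annual_rate_dvt_hosp,annual_rate_dvt_comm first
#'   event rates per 100 000 adult person-years.
#' @param triplet_compliance probability that a community DVT episode emits
#'   the full claim triplet (echo-Doppler, heparin, VKA); incomplete
#'   episodes drop one anticoagulant claim and are invisible to the
#'   detection algorithm by design.
#' @param heparin_lag_days,vka_lag_days claim-date offsets of the heparin
#'   and VKA deliveries after the echo-Doppler date.
#' @param noise_echo_rate,noise_heparin_rate per-adult-person-year rates of
#'   isolated echo-Doppler (surveillance) and heparin-only (prophylaxis)
#'   claims unrelated to any VTE; these never form a complete triplet.
#' @param recurrence_annual_prob,death_annual_prob named numeric over
#'   `PE`, `DVT_HOSP`, `DVT_COMM`.
#' @param recurrence_type_probs 3x3 matrix: rows index category, columns the
#'   category of a recurrence.
#' @param second_recurrence_prob,third_recurrence_prob probability of a
#'   further recurrence given the previous one.
#' @param recurrence_min_days minimum index-to-recurrence delay.
#' @param adult_fraction,female_fraction,adult_age_mean,adult_age_sd
#'   population mixture (adult ages are a normal clipped to 18-99; minors
#'   uniform 0-17).
#' @param covariate_prevalence named prevalences of risk-factor flags drawn
#'   (independently) for event persons; names must exist in the covariate
#'   map of the analysis config.
#' @param recurrence_hr named multiplicative effects of covariate flags on
#'   the recurrence hazard (default none).
#' @param hospital_or named multiplicative effects of covariate flags on the
#'   odds that a DVT is hospital- rather than community-managed
#'   (default none).
#' @param los_mean mean extra length of stay in days (Poisson).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_persons,
                       seed = 1L,
                       annual_rate_pe = 64.2,
                       annual_rate_dvt_hosp = 64.0,
                       annual_rate_dvt_comm = 55.8,
                       triplet_compliance = 1.0,
                       heparin_lag_days = 2L,
                       vka_lag_days = 5L,
                       noise_echo_rate = 0.02,
                       noise_heparin_rate = 0.02,
                       recurrence_annual_prob = c(PE = 0.076, DVT_HOSP = 0.044,
                                                  DVT_COMM = 0.044),
                       death_annual_prob = c(PE = 0.077, DVT_HOSP = 0.093,
                                             DVT_COMM = 0.009),
                       recurrence_type_probs = default_recurrence_type_probs(),
                       second_recurrence_prob = 0.12,
                       third_recurrence_prob = 0.03,
                       recurrence_min_days = 30L,
                       adult_fraction = 0.8,
                       female_fraction = 0.52,
                       adult_age_mean = 65,
                       adult_age_sd = 18,
                       covariate_prevalence = c(
                         prior_hospitalisation = 0.10, surgery = 0.03,
                         trauma = 0.04, hip_fracture = 0.005, cancer = 0.08,
                         obesity = 0.05, pregnancy = 0.01,
                         heart_failure = 0.04, renal_disease = 0.03,
                         gi_haemorrhage = 0.01, hormonal_therapy = 0.06),
                       recurrence_hr = numeric(0),
                       hospital_or = numeric(0),
                       los_mean = 5) {
  if (n_persons <= 0) stop("n_persons must be positive")
  probs <- c(triplet_compliance, adult_fraction, female_fraction,
             recurrence_annual_prob, death_annual_prob,
             second_recurrence_prob, third_recurrence_prob,
             covariate_prevalence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  rates <- c(annual_rate_pe, annual_rate_dvt_hosp, annual_rate_dvt_comm,
             noise_echo_rate, noise_heparin_rate)
  if (any(rates < 0)) stop("rates must be non-negative")
  for (v in list(recurrence_annual_prob, death_annual_prob))
    if (!setequal(names(v), EVENT_CATEGORIES))
      stop("per-category probabilities must be named PE, DVT_HOSP, DVT_COMM")
  stopifnot(is.matrix(recurrence_type_probs),
            all(abs(rowSums(recurrence_type_probs) - 1) < 1e-8))
  structure(as.list(environment()), class = "sim_params")
}

stage_seed <- function(params, stage) as.integer(params$seed) + stage

window_days <- function(config)
  as.integer(config$study_end - config$study_start) + 1L

window_years <- function(config) window_days(config) / 365.25

#' Generate a synthetic insured population
#'
#' Adults (at study start) and minors per the configured mixture; coverage
#' spans the lookback and follow-up horizons around the study window.
#' Death dates are filled in later from the truth log (only post-event
#' deaths are modelled).
#'
#' @param params a [sim_params()].
#' @param config a [study_config()].
#' @return data.table of person records.
#' @export
generate_population <- function(params, config = study_config()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params, 0L))
  n <- as.integer(params$n_persons)
  adult <- rbinom(n, 1L, params$adult_fraction) == 1L
  age <- integer(n)
  age[adult] <- pmin(pmax(round(rnorm(sum(adult), params$adult_age_mean,
                                      params$adult_age_sd)), 18L), 99L)
  age[!adult] <- sample(0:17, sum(!adult), replace = TRUE)
  ## birth date so that completed age at study_start equals `age`
  birth <- config$study_start - round(age * 365.25) -
    sample(0:364, n, replace = TRUE)
  persons <- data.table(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = ifelse(runif(n) < params$female_fraction, "F", "M"),
    birth_date = birth,
    death_date = as.Date(NA),
    coverage_start = config$study_start - config$lookback_days - 35L,
    coverage_end = config$study_end + config$followup_days + 35L)
  ## day-granular birth arithmetic can land a clipped 18-year-old on 17;
  ## nudge those just over the boundary
  a0 <- age_at(persons$birth_date, config$study_start)
  fix <- adult & a0 < config$adult_age_min
  persons$birth_date[fix] <- persons$birth_date[fix] - 366L
  setkey(persons, person_id)
  persons[]
}

sample_category <- function(n, probs) {
  ## vectorised categorical draw over EVENT_CATEGORIES
  u <- runif(n)
  cm <- matrix(rep(cumsum(probs), each = n), nrow = n)
  EVENT_CATEGORIES[1L + rowSums(u > cm)]
}

#' Draw the ground-truth event history
#'
#' Per adult and per category, a first event is drawn with probability
#' `rate x window_years / 100 000` at a date uniform over the study window
#' (DVT events drawn at the combined rate, then assigned a setting by a
#' per-person logistic model whose baseline reproduces the configured
#' hospital/community split). Recurrences within the follow-up horizon and
#' post-index deaths follow the per-category probabilities; events after
#' death are discarded.
#'
#' @param persons population table from [generate_population()].
#' @param params a [sim_params()]; @param config a [study_config()].
#' @return object of class `truth_log`: list with `events` (primary and
#'   recurrent, with category and date), `index` (one row per cohort
#'   person: index date/category, recurrence and death dates), and
#'   `covariates` (risk-factor flags of event persons).
#' @export
generate_truth <- function(persons, params, config = study_config()) {
  set.seed(stage_seed(params, 1L))
  yrs <- window_years(config)
  nd <- window_days(config)
  adults <- persons[age_at(birth_date, config$study_start) >=
                      config$adult_age_min]
  na <- nrow(adults)

  p_pe <- params$annual_rate_pe * yrs / 1e5
  r_h <- params$annual_rate_dvt_hosp; r_c <- params$annual_rate_dvt_comm
  p_dvt <- (r_h + r_c) * yrs / 1e5
  base_hosp <- if (r_h + r_c > 0) r_h / (r_h + r_c) else 0.5

  draw_events <- function(p) {
    hit <- which(rbinom(na, 1L, min(p, 1)) == 1L)
    data.table(person_id = adults$person_id[hit],
               event_date = config$study_start +
                 sample.int(nd, length(hit), replace = TRUE) - 1L)
  }
  pe <- draw_events(p_pe)
  if (nrow(pe) > 0L) pe[, `:=`(vte_type = "PE", setting = "HOSPITAL")]
  dvt <- draw_events(p_dvt)

  event_persons <- unique(c(pe$person_id, dvt$person_id))
  cov_names <- names(params$covariate_prevalence)
  covariates <- data.table(person_id = event_persons)
  for (nm in cov_names)
    covariates[[nm]] <- rbinom(length(event_persons), 1L,
                               params$covariate_prevalence[[nm]]) == 1L
  setkey(covariates, person_id)

  log_or_sum <- function(ids, effects) {
    if (length(effects) == 0L || length(ids) == 0L) return(numeric(length(ids)))
    flags <- covariates[J(ids), on = "person_id"]
    s <- numeric(length(ids))
    for (nm in names(effects)) {
      if (!nm %in% names(flags))
        stop("effect refers to unknown covariate: ", nm)
      s <- s + ifelse(flags[[nm]], log(effects[[nm]]), 0)
    }
    s
  }

  if (nrow(dvt) > 0L) {
    p_hosp <- plogis(qlogis(base_hosp) + log_or_sum(dvt$person_id,
                                                    params$hospital_or))
    dvt[, `:=`(vte_type = "DVT",
               setting = ifelse(runif(.N) < p_hosp, "HOSPITAL", "COMMUNITY"))]
  }
  events <- rbind(pe, dvt, fill = TRUE)
  if (nrow(events) == 0L) {
    empty <- data.table(person_id = character(), event_date = as.Date(character()),
                        vte_type = character(), setting = character(),
                        category = character(), role = character())
    empty_idx <- data.table(person_id = character(),
                            index_date = as.Date(character()),
                            index_category = character(),
                            death_date = as.Date(character()))
    return(structure(list(events = empty, index = empty_idx,
                          covariates = covariates),
                     class = "truth_log"))
  }
  events[, category := ifelse(vte_type == "PE", "PE",
                              ifelse(setting == "HOSPITAL", "DVT_HOSP",
                                     "DVT_COMM"))]
  events[, role := "PRIMARY"]

  ## index = earliest event (PE wins a same-day tie, then hospital DVT)
  events[, priority := match(category, EVENT_CATEGORIES)]
  setorder(events, person_id, event_date, priority)
  index <- events[, .SD[1L], by = person_id,
                  .SDcols = c("event_date", "category")]
  setnames(index, c("event_date", "category"), c("index_date", "index_category"))

  ## 12-month recurrence, with covariate effects on the hazard
  p0 <- params$recurrence_annual_prob[index$index_category]
  mult <- exp(log_or_sum(index$person_id, params$recurrence_hr))
  p_rec <- 1 - (1 - p0)^mult
  gap <- params$recurrence_min_days
  fu <- config$followup_days
  draw_delay <- function(n, lo) floor(runif(n, lo + 1, fu + 1))

  rec_list <- list()
  active <- which(rbinom(nrow(index), 1L, p_rec) == 1L)
  delay_prev <- rep(NA_integer_, nrow(index))
  stage_p <- c(1.0, params$second_recurrence_prob, params$third_recurrence_prob)
  take <- active
  prev_delay <- rep(0L, nrow(index))
  for (k in 1:3) {
    if (length(take) == 0L) break
    if (k > 1L) {
      keep <- take[rbinom(length(take), 1L, stage_p[k]) == 1L]
      take <- keep[prev_delay[keep] + gap + 1L <= fu]
      if (length(take) == 0L) break
    }
    lo <- pmax(prev_delay[take] + gap, gap)
    delay <- floor(runif(length(take), lo + 1, fu + 1))
    cat_k <- character(length(take))
    for (ic in EVENT_CATEGORIES) {
      sel <- index$index_category[take] == ic
      if (any(sel))
        cat_k[sel] <- sample_category(sum(sel),
                                      params$recurrence_type_probs[ic, ])
    }
    rec_list[[k]] <- data.table(
      person_id = index$person_id[take],
      event_date = index$index_date[take] + delay,
      category = cat_k, role = "RECURRENCE")
    prev_delay[take] <- delay
  }
  recurrences <- rbindlist(rec_list)

  ## post-index death; truncates later recurrences
  p_death <- params$death_annual_prob[index$index_category]
  died <- rbinom(nrow(index), 1L, p_death) == 1L
  index[, death_date := as.Date(NA)]
  index[died, death_date := index_date + sample.int(fu, sum(died),
                                                    replace = TRUE)]
  if (nrow(recurrences) > 0L) {
    recurrences <- merge(recurrences,
                         index[, .(person_id, death_date)],
                         by = "person_id", all.x = TRUE)
    recurrences <- recurrences[is.na(death_date) | event_date <= death_date]
    recurrences[, death_date := NULL]
  }
  if (nrow(recurrences) > 0L) {
    recurrences[, vte_type := ifelse(category == "PE", "PE", "DVT")]
    recurrences[, setting := ifelse(category == "DVT_COMM", "COMMUNITY",
                                    "HOSPITAL")]
  }
  events[, priority := NULL]
  all_events <- rbind(events, recurrences, fill = TRUE)
  setorder(all_events, person_id, event_date)
  structure(list(events = all_events[], index = index[],
                 covariates = covariates),
            class = "truth_log")
}

#' Emit claims and hospital stays from a truth log
#'
#' Hospital events (all PE; hospital DVT) become stays whose diagnosis set
#' contains a qualifying ICD-10 code, as primary diagnosis or (with
#' probability 0.25) as associated diagnosis under an unrelated primary.
#' Community DVT events become the claim triplet echo-Doppler at T0,
#' heparin/fondaparinux at T0 + `heparin_lag_days`, VKA at T0 +
#' `vka_lag_days`, with probability `triplet_compliance`; otherwise one
#' anticoagulant claim is dropped. Claim and discharge dates are clipped at
#' the death date. Risk-factor flags of index persons are materialised as
#' lookback stays/claims per the covariate map.
#'
#' @param truth a `truth_log`; @param persons the population table;
#' @param params a [sim_params()]; @param config a [study_config()].
#' @return list with data.tables `claims` and `stays` (each carrying an
#'   internal `origin` column: event / covariate).
#' @export
emit_claims <- function(truth, persons, params, config = study_config()) {
  set.seed(stage_seed(params, 2L))
  if (params$triplet_compliance == 1 &&
      (params$heparin_lag_days > config$rule$heparin_window_days ||
       params$vka_lag_days > config$rule$vka_window_days))
    warning("claim lags exceed the detection windows: community events ",
            "will be missed by design")
  ev <- copy(truth$events)
  death <- if (nrow(truth$index) > 0L)
    truth$index[, .(person_id, death_date)] else
      data.table(person_id = character(), death_date = as.Date(character()))
  if (nrow(ev) > 0L)
    ev <- merge(ev, death, by = "person_id", all.x = TRUE)

  clip <- function(d, dd) as.Date(ifelse(!is.na(dd) & d > dd, dd, d),
                                  origin = "1970-01-01")

  ## hospital stays for PE and hospital DVT events
  hosp <- ev[setting == "HOSPITAL"]
  stays <- data.table(person_id = character(), admission_date = as.Date(character()),
                      discharge_date = as.Date(character()),
                      primary_dx = character(), associated_dx = character(),
                      origin = character())
  if (nrow(hosp) > 0L) {
    n <- nrow(hosp)
    code <- ifelse(hosp$vte_type == "PE",
                   sample(config$code_set$pe_codes, n, replace = TRUE),
                   sample(config$code_set$dvt_codes, n, replace = TRUE))
    as_primary <- runif(n) < 0.75
    extra <- ifelse(runif(n) < 0.3, "I10", "")
    primary <- ifelse(as_primary, code, "J18.9")
    assoc <- ifelse(as_primary, extra,
                    ifelse(extra == "", code, paste(code, extra, sep = DX_SEP)))
    los <- rpois(n, params$los_mean) + 1L
    stays <- data.table(person_id = hosp$person_id,
                        admission_date = hosp$event_date,
                        discharge_date = clip(hosp$event_date + los,
                                              hosp$death_date),
                        primary_dx = primary, associated_dx = assoc,
                        origin = "event")
  }

  ## community DVT triplets
  comm <- ev[setting == "COMMUNITY"]
  claims_parts <- list()
  if (nrow(comm) > 0L) {
    n <- nrow(comm)
    complete <- runif(n) < params$triplet_compliance
    hep_class <- ifelse(runif(n) < 0.9, "LMWH", "FONDAPARINUX")
    drop_vka <- runif(n) < 0.5  # which claim an incomplete episode lacks
    presc <- function(m) sample(c("GP", "SPECIALIST", "HOSPITAL"), m,
                                replace = TRUE, prob = c(0.85, 0.10, 0.05))
    echo <- data.table(person_id = comm$person_id,
                       service_date = comm$event_date,
                       service_class = "ECHO_DOPPLER", prescriber = presc(n))
    hep_keep <- complete | drop_vka   # an incomplete episode dropping VKA keeps heparin
    hep <- data.table(person_id = comm$person_id,
                      service_date = clip(comm$event_date +
                                            params$heparin_lag_days,
                                          comm$death_date),
                      service_class = hep_class,
                      prescriber = presc(n))[hep_keep]
    vka_keep <- complete | !drop_vka
    vka <- data.table(person_id = comm$person_id,
                      service_date = clip(comm$event_date + params$vka_lag_days,
                                          comm$death_date),
                      service_class = "VKA", prescriber = presc(n))[vka_keep]
    claims_parts$triplet <- rbind(echo, hep, vka)[, origin := "event"]
  }

  ## lookback materialisation of the covariate flags of index persons
  if (nrow(truth$index) > 0L && nrow(truth$covariates) > 0L) {
    idx <- merge(truth$index, truth$covariates, by = "person_id")
    for (nm in intersect(names(params$covariate_prevalence),
                         names(config$covariates))) {
      def <- config$covariates[[nm]]
      who <- idx[idx[[nm]] == TRUE]
      if (nrow(who) == 0L) next
      m <- nrow(who)
      offset <- floor(runif(m, 15, config$lookback_days - 15))
      when <- who$index_date - offset
      if (identical(def$kind, "claim")) {
        claims_parts[[nm]] <- data.table(
          person_id = who$person_id, service_date = when,
          service_class = def$class, prescriber = "GP", origin = "covariate")
      } else {
        code <- if (identical(def$kind, "any_stay")) rep("J18.9", m) else
          sample(def$codes, m, replace = TRUE)
        dis <- pmin(when + rpois(m, 3) + 1L, who$index_date - 1L)
        stays <- rbind(stays, data.table(
          person_id = who$person_id, admission_date = when,
          discharge_date = dis, primary_dx = code, associated_dx = "",
          origin = "covariate"))
      }
    }
  }
  claims <- rbindlist(claims_parts, use.names = TRUE, fill = TRUE)
  if (is.null(claims) || nrow(claims) == 0L)
    claims <- data.table(person_id = character(),
                         service_date = as.Date(character()),
                         service_class = character(), prescriber = character(),
                         origin = character())
  setorder(claims, person_id, service_date, service_class)
  setorder(stays, person_id, admission_date)
  list(claims = claims[], stays = stays[])
}

#' Add non-VTE claim noise
#'
#' Per adult, Poisson numbers of isolated echo-Doppler claims (surveillance
#' imaging) and heparin-only claims (prophylaxis) at the configured
#' per-person-year rates, at dates uniform over the study window. No VKA
#' noise is generated, so noise alone never completes a detection triplet.
#'
#' @param claims claims table to extend; @param persons population table;
#' @param params a [sim_params()]; @param config a [study_config()].
#' @return the claims table with noise rows appended (`origin = "noise"`).
#' @export
inject_noise <- function(claims, persons, params, config = study_config()) {
  set.seed(stage_seed(params, 3L))
  yrs <- window_years(config)
  nd <- window_days(config)
  adults <- persons[age_at(birth_date, config$study_start) >=
                      config$adult_age_min]
  mk <- function(rate, class) {
    k <- rpois(nrow(adults), rate * yrs)
    tot <- sum(k)
    if (tot == 0L) return(NULL)
    data.table(person_id = rep(adults$person_id, k),
               service_date = config$study_start +
                 sample.int(nd, tot, replace = TRUE) - 1L,
               service_class = class,
               prescriber = sample(c("GP", "SPECIALIST", "UNKNOWN"), tot,
                                   replace = TRUE, prob = c(0.7, 0.2, 0.1)),
               origin = "noise")
  }
  noise <- rbindlist(list(mk(params$noise_echo_rate, "ECHO_DOPPLER"),
                          mk(params$noise_heparin_rate, "LMWH")))
  out <- rbind(claims, noise, fill = TRUE)
  setorder(out, person_id, service_date, service_class)
  out[]
}

#' Simulate a complete synthetic claims dataset
#'
#' Runs [generate_population()], [generate_truth()], [emit_claims()] and
#' [inject_noise()], fills person death dates from the truth log, and
#' returns the validated dataset together with the truth log.
#'
#' @param params a [sim_params()]; @param config a [study_config()].
#' @return list with `dataset` (a `claims_dataset`) and `truth`
#'   (a `truth_log`).
#' @export
simulate_claims <- function(params, config = study_config()) {
  persons <- generate_population(params, config)
  truth <- generate_truth(persons, params, config)
  emitted <- emit_claims(truth, persons, params, config)
  claims <- inject_noise(emitted$claims, persons, params, config)
  if (nrow(truth$index) > 0L) {
    persons[truth$index, death_date := i.death_date, on = "person_id"]
  }
  list(dataset = claims_dataset(persons, claims, emitted$stays),
       truth = truth)
}
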
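cfg <- study_config()
cs <- vte_code_set()

test_that("hospital capture reads primary and associated diagnoses", {
  st <- make_stays(c("P001", "P002", "P003", "P004"), c(10L, 20L, 30L, 40L),
                   c("I26.0", "J18.9", "I26.9", "K52.9"),
                   c("", "I80.2", "I80.3", ""))
  ev <- find_hospital_events(st, cs)
  expect_identical(nrow(ev), 3L)
  expect_identical(ev[ev$person_id == "P001"]$vte_type, "PE")
  expect_identical(ev[ev$person_id == "P001"]$source_kind, "PRIMARY_DX")
  expect_identical(ev[ev$person_id == "P002"]$vte_type, "DVT")
  expect_identical(ev[ev$person_id == "P002"]$source_kind, "ASSOCIATED_DX")
  ## both code sets on one stay: a single PE event
  expect_identical(ev[ev$person_id == "P003"]$vte_type, "PE")
  expect_identical(ev$event_date, as.Date("2010-01-01") + c(10L, 20L, 30L))
})

comm_find <- function(days, classes, rule = episode_rule()) {
  find_community_dvt(make_claims("P001", days, classes), rule)
}

test_that("the three-criterion community algorithm enforces windows and order", {
  ## echo d100, heparin d103, VKA d106: event indexed at the echo date
  ev <- comm_find(c(100L, 103L, 106L), c("ECHO_DOPPLER", "LMWH", "VKA"))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$event_date, as.Date("2010-01-01") + 100L)
  expect_identical(ev$source_kind, "ALGORITHM")
  ## heparin outside +/- 7
  expect_identical(nrow(comm_find(c(100L, 110L, 106L),
                                  c("ECHO_DOPPLER", "LMWH", "VKA"))), 0L)
  ## VKA before the echo violates the order
  expect_identical(nrow(comm_find(c(100L, 98L, 101L),
                                  c("ECHO_DOPPLER", "VKA", "LMWH"))), 0L)
  ## fondaparinux qualifies; same-day tie and day-7 boundary included
  ev <- comm_find(c(100L, 100L, 107L),
                  c("ECHO_DOPPLER", "FONDAPARINUX", "VKA"))
  expect_identical(nrow(ev), 1L)
  ## VKA later than day 7: no event
  expect_identical(nrow(comm_find(c(100L, 100L, 108L),
                                  c("ECHO_DOPPLER", "FONDAPARINUX", "VKA"))),
                   0L)
  ## heparin must not precede the echo even inside the +/- window
  expect_identical(nrow(comm_find(c(100L, 97L, 104L),
                                  c("ECHO_DOPPLER", "LMWH", "VKA"))), 0L)
})

test_that("an echo inside a detected episode does not start a second event", {
  ev <- comm_find(c(100L, 102L, 103L, 105L),
                  c("ECHO_DOPPLER", "LMWH", "ECHO_DOPPLER", "VKA"))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$event_date, as.Date("2010-01-01") + 100L)
  ## two well-separated episodes are both found
  ev2 <- comm_find(c(100L, 102L, 105L, 300L, 302L, 305L),
                   rep(c("ECHO_DOPPLER", "LMWH", "VKA"), 2))
  expect_identical(nrow(ev2), 2L)
})

adjudicate_small <- function(events_spec, persons = make_persons(1)) {
  hosp <- events_spec[events_spec$setting == "HOSPITAL", ]
  comm <- events_spec[events_spec$setting == "COMMUNITY", ]
  mk <- function(d) if (nrow(d) == 0L) NULL else
    data.frame(person_id = d$person_id, event_date = d$event_date,
               vte_type = d$vte_type, setting = d$setting,
               source_kind = ifelse(d$setting == "COMMUNITY", "ALGORITHM",
                                    "PRIMARY_DX"))
  adjudicate_index_events(mk(hosp), mk(comm), persons, cfg)
}

espec <- function(person, days, type, setting,
                  base = as.Date("2010-01-01")) {
  data.frame(person_id = person, event_date = base + days, vte_type = type,
             setting = setting)
}

test_that("clot migration collapses a DVT into the following PE", {
  adj <- adjudicate_small(espec("P001", c(100L, 110L), c("DVT", "PE"),
                                c("COMMUNITY", "HOSPITAL")))
  expect_identical(nrow(adj$events), 1L)
  expect_identical(adj$events$category, "PE")
  expect_identical(adj$cohort$index_category, "PE")
  ## beyond the migration window both events stand
  adj2 <- adjudicate_small(espec("P001", c(100L, 140L), c("DVT", "PE"),
                                 c("COMMUNITY", "HOSPITAL")))
  expect_identical(nrow(adj2$events), 2L)
  expect_identical(adj2$cohort$index_category, "DVT_COMM")
})

test_that("community DVT then hospital DVT reclassifies, keeping the early index", {
  adj <- adjudicate_small(espec("P001", c(100L, 115L), c("DVT", "DVT"),
                                c("COMMUNITY", "HOSPITAL")))
  expect_identical(nrow(adj$events), 1L)
  expect_identical(adj$events$category, "DVT_HOSP")
  expect_identical(adj$cohort$index_date, as.Date("2010-01-01") + 100L)
  expect_identical(adj$cohort$index_category, "DVT_HOSP")
})

test_that("independent events both count; the cohort keeps the first as index", {
  adj <- adjudicate_small(espec("P001", c(50L, 400L), c("DVT", "DVT"),
                                c("HOSPITAL", "HOSPITAL")))
  expect_identical(nrow(adj$events), 2L)
  expect_identical(nrow(adj$cohort), 1L)
  expect_identical(adj$cohort$index_date, as.Date("2010-01-01") + 50L)
})

test_that("non-adults at the event date are excluded", {
  minors <- make_persons(1, birth = "1995-06-01")
  adj <- adjudicate_small(espec("P001", 100L, "PE", "HOSPITAL"),
                          persons = minors)
  expect_identical(nrow(adj$events), 0L)
  expect_identical(nrow(adj$cohort), 0L)
})

test_that("adjudication is order-independent and same-day ties prefer PE", {
  sp <- espec("P001", c(200L, 200L), c("DVT", "PE"),
              c("HOSPITAL", "HOSPITAL"))
  a1 <- adjudicate_small(sp)
  a2 <- adjudicate_small(sp[2:1, ])
  expect_identical(a1$events, a2$events)
  expect_identical(a1$events$category, "PE")
})

test_that("every adjudicated PE is hospital-managed", {
  p <- sim_params(n_persons = 30000, seed = 31)
  sim <- simulate_claims(p, cfg)
  res <- build_cohort(sim$dataset, cfg)
  expect_true(all(res$events[res$events$vte_type == "PE"]$setting ==
                    "HOSPITAL"))
  expect_true(all(res$cohort$index_date >= cfg$study_start &
                    res$cohort$index_date <= cfg$study_end))
  expect_true(all(res$cohort$age_at_index >= cfg$adult_age_min))
})

test_that("recurrence detection applies the blanking gap and death truncation", {
  persons <- make_persons(3)
  persons$death_date[3] <- as.Date("2010-01-01") + 80L
  sp <- rbind(espec("P001", c(0L, 90L), c("PE", "PE"),
                    c("HOSPITAL", "HOSPITAL")),
              espec("P002", c(0L, 10L), c("DVT", "DVT"),
                    c("HOSPITAL", "HOSPITAL")),
              espec("P003", c(0L, 100L), c("PE", "PE"),
                    c("HOSPITAL", "HOSPITAL")))
  ## use raw (unadjudicated-looking) events through the small helper
  adj <- adjudicate_small(sp, persons = persons)
  rec <- detect_recurrences(adj$cohort, adj$events, cfg)
  c1 <- rec$cohort[rec$cohort$person_id == "P001"]
  expect_identical(c1$n_recurrences, 1L)
  expect_identical(c1$first_recurrence_category, "PE")
  expect_identical(c1$time_to_event, 90L)
  ## day-10 event sits inside the 30-day blanking gap
  expect_identical(rec$cohort[person_id == "P002"]$n_recurrences, 0L)
  ## P003 died on day 80: the day-100 event is not a recurrence and the
  ## adjudicated table drops post-death events entirely
  expect_identical(rec$cohort[person_id == "P003"]$n_recurrences, 0L)
})

test_that("lookback covariates respect the 12-month window boundaries", {
  persons <- make_persons(2)
  sp <- espec(c("P001", "P002"), c(400L, 400L), "PE", "HOSPITAL")
  adj <- adjudicate_small(sp, persons = persons)
  base <- as.Date("2010-01-01")
  stays <- make_stays("P001", 220L, "C34.9")            # ~6 months before
  claims <- make_claims("P002", 400L - 396L, "HORMONAL_THERAPY")  # 13 months
  cohort <- extract_covariates(adj$cohort, claims, stays, cfg)
  expect_true(cohort[person_id == "P001"]$cancer)
  expect_true(cohort[person_id == "P001"]$prior_hospitalisation)
  expect_false(cohort[person_id == "P001"]$prior_hospitalisation_90d)
  expect_false(cohort[person_id == "P002"]$hormonal_therapy)
  expect_false(cohort[person_id == "P002"]$prior_hospitalisation)
})

test_that("the finder recovers the truth log exactly under ideal conditions", {
  p <- sim_params(n_persons = 50000, seed = 37, triplet_compliance = 1,
                  noise_echo_rate = 0, noise_heparin_rate = 0)
  sim <- simulate_claims(p, cfg)
  det <- find_community_dvt(sim$dataset$claims, cfg$rule)
  truth_comm <- sim$truth$events[sim$truth$events$category == "DVT_COMM", ]
  expect_setequal(paste(det$person_id, det$event_date),
                  paste(truth_comm$person_id, truth_comm$event_date))
})
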
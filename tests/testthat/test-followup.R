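test_that("proportions reproduce the published cohort percentages", {
  p1 <- proportion_with_ci(99, 1804)
  expect_equal(round(p1$percent, 1), 5.5)
  p2 <- proportion_with_ci(112, 1804)
  expect_equal(round(p2$percent, 1), 6.2)
  expect_true(p2$ci_low <= p2$percent && p2$percent <= p2$ci_high)
  p0 <- proportion_with_ci(0, 50)
  expect_identical(p0$percent, 0)
  expect_identical(p0$ci_low, 0)
  expect_error(proportion_with_ci(51, 50), "k must lie")
})

test_that("chi-square matches the hand formula and its invariances", {
  tab <- rbind(c(47, 28, 24), c(575, 605, 525))
  res <- pearson_chi2(tab)
  ## oracle: direct sum((O-E)^2/E)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(res$p, pchisq(res$statistic, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  ## permutation invariance
  res2 <- pearson_chi2(tab[, c(3, 1, 2)])
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  ## linear scaling of all counts
  res3 <- pearson_chi2(3 * tab)
  expect_equal(res3$statistic, 3 * res$statistic, tolerance = 1e-9)

  ## identical group proportions: statistic 0, p 1
  flat <- rbind(c(10, 20), c(30, 60))
  expect_equal(pearson_chi2(flat)$statistic, 0, tolerance = 1e-12)
  expect_equal(pearson_chi2(flat)$p, 1)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "zero row")
})

test_that("Fisher exact p agrees with brute-force enumeration", {
  ## diagonal 2x2: three tables share the margins, two are extreme
  expect_equal(fisher_exact_rxc(rbind(c(2, 0), c(0, 2))), 1 / 3,
               tolerance = 1e-9)
  ## degenerate margin
  expect_identical(fisher_exact_rxc(rbind(c(0, 0), c(3, 2))), 1)

  set.seed(42)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab), fisher_oracle(tab),
                 tolerance = 1e-7, label = paste("table", i))
  }
  ## r x c case
  tab3 <- rbind(c(5, 1, 2), c(0, 4, 3))
  expect_equal(fisher_exact_rxc(tab3), fisher_oracle(tab3), tolerance = 1e-7)
  expect_error(fisher_exact_rxc(matrix(c(300, 300, 300, 300), 2)),
               "exceeds the exact-mode guard")
})

test_that("Fisher and chi-square agree asymptotically on 2x2 decisions", {
  ## spot checks with all cells >= 50: homogeneous and strongly associated
  ## tables, where the exact and asymptotic p-values converge
  tabs <- list(matrix(c(100L, 100L, 100L, 100L), 2),
               matrix(c(140L, 60L, 80L, 120L), 2),
               matrix(c(130L, 70L, 95L, 105L), 2),
               matrix(c(200L, 50L, 120L, 130L), 2))
  for (tab in tabs) {
    pf <- fisher_exact_rxc(tab, max_total = 1e6)
    pc <- pearson_chi2(tab)$p
    expect_lt(abs(pf - pc), 0.02)
    expect_identical(pf < 0.05, pc < 0.05)
  }
})

test_that("Kaplan-Meier matches the hand product-limit and the ECDF", {
  ## (5, event), (8, censored), (12, event)
  km <- km_estimate(c(5, 8, 12), c(1, 0, 1))
  oracle <- km_oracle(c(5, 8, 12), c(1, 0, 1))
  expect_equal(km$survival[km$time %in% oracle$time], oracle$surv,
               tolerance = 1e-12)
  expect_equal(km$survival[km$time == 12], 0, tolerance = 1e-12)

  ## no censoring: 1 - S equals the empirical CDF
  set.seed(11)
  tt <- sample(1:50, 30, replace = TRUE)
  km2 <- km_estimate(tt, rep(1, 30))
  ecdf_fun <- ecdf(tt)
  expect_equal(km2$cuminc, as.numeric(ecdf_fun(km2$time)), tolerance = 1e-12)

  ## all censored: survival stays 1
  km3 <- km_estimate(c(3, 9, 20), c(0, 0, 0))
  expect_true(all(km3$cuminc == 0))
  expect_error(km_estimate(c(-1, 3), c(1, 1)), "negative")

  ## step-function evaluation
  at <- km_at(km, c(4, 5, 11, 12, 400))
  expect_equal(at$cuminc, c(0, 1 / 3, 1 / 3, 1, 1), tolerance = 1e-12)
})

test_that("the follow-up report reproduces published group statistics", {
  ## cohort shaped like the published one: groups 622/633/549 with
  ## 47/28/24 recurrences and 48/59/5 deaths
  n <- c(PE = 622L, DVT_HOSP = 633L, DVT_COMM = 549L)
  k <- c(PE = 47L, DVT_HOSP = 28L, DVT_COMM = 24L)
  d <- c(PE = 48L, DVT_HOSP = 59L, DVT_COMM = 5L)
  base <- as.Date("2010-06-01")
  rows <- lapply(names(n), function(g) {
    nn <- n[[g]]; kk <- k[[g]]; dd <- d[[g]]
    data.table::data.table(
      person_id = sprintf("%s%04d", g, seq_len(nn)),
      index_date = base, index_category = g,
      age_at_index = 70L, sex = "F",
      death_date = c(base + 200L + seq_len(dd) %% 100L,
                     rep(as.Date(NA), nn - dd)),
      censor_date = base + 365L,
      n_recurrences = c(rep(1L, kk), rep(0L, nn - kk)),
      first_recurrence_date = c(base + 90L + seq_len(kk) %% 200L,
                                rep(as.Date(NA), nn - kk)),
      first_recurrence_category = c(rep(g, kk), rep(NA_character_, nn - kk)))
  })
  cohort <- data.table::rbindlist(rows)
  cohort[, event_status := as.integer(n_recurrences > 0L)]
  cohort[, time_to_event := data.table::fifelse(
    event_status == 1L, as.integer(first_recurrence_date - index_date), 365L)]
  recurrences <- cohort[n_recurrences > 0L,
                        .(person_id, recurrence_date = first_recurrence_date,
                          recurrence_category = first_recurrence_category)]
  rep <- followup_report(cohort, recurrences, study_config())

  props <- rep$recurrence$proportions
  expect_equal(round(props$PE$percent, 1), 7.6)
  expect_equal(round(props$DVT_HOSP$percent, 1), 4.4)
  expect_equal(round(props$DVT_COMM$percent, 1), 4.4)
  expect_equal(round(props$ALL$percent, 1), 5.5)
  expect_equal(round(rep$recurrence$chi2$p, 2), 0.02)

  mort <- rep$mortality$proportions
  expect_equal(round(mort$PE$percent, 1), 7.7)
  expect_equal(round(mort$DVT_HOSP$percent, 1), 9.3)
  expect_equal(round(mort$DVT_COMM$percent, 1), 0.9)
  expect_equal(round(mort$ALL$percent, 1), 6.2)
  expect_lt(rep$mortality$dvt_setting_chi2$p, 0.001)

  ## KM with no late entry: cuminc at day 365 >= crude proportion scale
  marks <- rep$km_death$at_months
  all365 <- marks[marks$group == "ALL" & marks$time == 365, ]
  expect_gt(all365$cuminc, 0.05)
  expect_lt(all365$cuminc, 0.08)
})

test_that("chi-square keeps its nominal size on null recurrence tables", {
  set.seed(1)
  nsim <- 200
  rejected <- 0L
  for (i in seq_len(nsim)) {
    k <- rbinom(3, c(620, 630, 550), 0.05)
    tab <- rbind(k, c(620, 630, 550) - k)
    if (pearson_chi2(tab)$p < 0.05) rejected <- rejected + 1L
  }
  expect_gte(rejected / nsim, 0.03)
  expect_lte(rejected / nsim, 0.07)
})
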
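## small cohort builders with controllable effects ---------------------------

make_surv_cohort <- function(n, hr = 1, prevalence = 0.3, base_haz = 1 / 400,
                             admin_cens = 365L) {
  x <- rbinom(n, 1, prevalence) == 1
  t_ev <- rexp(n, base_haz * ifelse(x, hr, 1))
  data.table::data.table(
    person_id = sprintf("S%05d", seq_len(n)),
    index_category = sample(c("PE", "DVT_HOSP", "DVT_COMM"), n, TRUE),
    time_to_event = pmin(ceiling(t_ev), admin_cens),
    event_status = as.integer(t_ev <= admin_cens),
    flag = x)
}

make_binary_cohort <- function(n, or = 1, prevalence = 0.3, base_p = 0.5) {
  x <- rbinom(n, 1, prevalence) == 1
  p <- plogis(qlogis(base_p) + log(or) * x)
  data.table::data.table(
    person_id = sprintf("B%05d", seq_len(n)),
    index_category = ifelse(rbinom(n, 1, p) == 1, "DVT_HOSP", "DVT_COMM"),
    flag = x)
}

test_that("logistic on one binary covariate reproduces the ad/bc odds ratio", {
  tab <- matrix(c(30L, 14L, 22L, 41L), 2)  # a c / b d by column
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  cohort <- data.table::data.table(
    index_category = rep(c("DVT_HOSP", "DVT_COMM", "DVT_HOSP", "DVT_COMM"),
                         c(a, b, c_, d)),
    flag = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c_, d)))
  res <- fit_logistic_model(cohort, "flag")
  expect_equal(res$terms$ratio, (a * d) / (b * c_), tolerance = 1e-6)
})

test_that("logistic edge cases: intercept-only prevalence; separation error", {
  set.seed(3)
  cohort <- make_binary_cohort(400, or = 1)
  res0 <- fit_logistic_model(cohort, character(0))
  expect_equal(plogis(res0$terms$estimate),
               mean(cohort$index_category == "DVT_HOSP"), tolerance = 1e-8)
  sep <- data.table::data.table(
    index_category = rep(c("DVT_HOSP", "DVT_COMM"), each = 20),
    flag = rep(c(TRUE, FALSE), each = 20))
  expect_error(fit_logistic_model(sep, "flag"), "separat")
})

test_that("logistic CI covers the null in about 95% of null simulations", {
  set.seed(5)
  cover <- 0L
  nsim <- 200
  for (i in seq_len(nsim)) {
    cohort <- make_binary_cohort(300, or = 1)
    res <- tryCatch(fit_logistic_model(cohort, "flag"),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (res$terms$ci_low <= 1 && 1 <= res$terms$ci_high) cover <- cover + 1L
  }
  expect_gt(cover / nsim, 0.90)
})

test_that("Cox coefficient matches a brute-force partial-likelihood grid", {
  ## six subjects, untied times
  time <- c(4, 7, 10, 15, 21, 30)
  status <- c(1, 1, 0, 1, 1, 0)
  x <- c(1, 0, 1, 1, 0, 0)
  cohort <- data.table::data.table(person_id = as.character(1:6),
                                   index_category = "PE",
                                   time_to_event = time,
                                   event_status = status, flag = x == 1)
  res <- fit_cox_model(cohort, "flag", ties = "breslow")
  beta_hat <- cox_grid_oracle(time, status, x)
  expect_equal(res$terms$estimate, beta_hat, tolerance = 2e-3)
})

test_that("Cox symmetry and time-shift invariance", {
  ## identical event-time patterns in both covariate groups
  cohort <- data.table::data.table(
    person_id = as.character(1:8), index_category = "PE",
    time_to_event = rep(c(10, 20, 30, 40), 2),
    event_status = rep(c(1, 1, 1, 0), 2),
    flag = rep(c(TRUE, FALSE), each = 4))
  res <- fit_cox_model(cohort, "flag")
  expect_equal(res$terms$estimate, 0, tolerance = 1e-8)

  set.seed(8)
  cohort2 <- make_surv_cohort(300, hr = 2)
  r1 <- fit_cox_model(cohort2, "flag")
  cohort3 <- data.table::copy(cohort2)[, time_to_event := time_to_event + 50]
  r2 <- fit_cox_model(cohort3, "flag")
  expect_equal(r1$terms$estimate, r2$terms$estimate, tolerance = 1e-8)
})

test_that("both models recover configured effects within 3 SE across seeds", {
  for (seed in 1:5) {
    set.seed(seed)
    sc <- make_surv_cohort(2000, hr = 2)
    rc <- fit_cox_model(sc, "flag")
    se_c <- (log(rc$terms$ci_high) - log(rc$terms$ci_low)) / (2 * 1.96)
    expect_lt(abs(rc$terms$estimate - log(2)), 3 * se_c)

    bc <- make_binary_cohort(2000, or = 2.5)
    rb <- fit_logistic_model(bc, "flag")
    se_b <- (log(rb$terms$ci_high) - log(rb$terms$ci_low)) / (2 * 1.96)
    expect_lt(abs(rb$terms$estimate - log(2.5)), 3 * se_b)
  }
})

test_that("univariate screen: size under the null, power under a real effect", {
  set.seed(13)
  nsim <- 200
  hits_null <- 0L
  for (i in seq_len(nsim)) {
    cohort <- make_surv_cohort(2000, hr = 1)
    spec <- model_spec("RECURRENCE_TIME_TO_EVENT", "flag")
    if (length(screen_univariate(cohort, spec)) > 0L) hits_null <- hits_null + 1L
  }
  expect_gt(hits_null / nsim, 0.01)
  expect_lt(hits_null / nsim, 0.10)

  hits_eff <- 0L
  for (i in 1:40) {
    cohort <- make_surv_cohort(2000, hr = 3)
    spec <- model_spec("RECURRENCE_TIME_TO_EVENT", "flag")
    if (length(screen_univariate(cohort, spec)) > 0L) hits_eff <- hits_eff + 1L
  }
  expect_gt(hits_eff / 40, 0.95)
})

test_that("the two-step procedure composes screen and fit consistently", {
  spec0 <- model_spec("RECURRENCE_TIME_TO_EVENT", character(0))
  set.seed(21)
  cohort <- make_surv_cohort(500, hr = 1)
  res0 <- two_step_procedure(cohort, spec0)
  expect_identical(nrow(res0$terms), 0L)
  expect_match(res0$notice, "no covariate")

  ## exactly one retained: multivariate equals univariate
  cohort2 <- make_surv_cohort(2000, hr = 3)
  spec1 <- model_spec("RECURRENCE_TIME_TO_EVENT", "flag")
  res1 <- two_step_procedure(cohort2, spec1)
  expect_identical(res1$retained, "flag")
  uni <- fit_cox_model(cohort2, "flag")
  expect_equal(res1$terms$estimate, uni$terms$estimate, tolerance = 1e-10)
})

test_that("configured hospitalisation effects are retained directionally", {
  set.seed(34)
  n <- 3000
  age_flag <- rbinom(n, 1, 0.5) == 1
  cancer <- rbinom(n, 1, 0.2) == 1
  p <- plogis(qlogis(0.5) + log(2.5) * age_flag + log(2) * cancer)
  cohort <- data.table::data.table(
    person_id = as.character(seq_len(n)),
    index_category = ifelse(rbinom(n, 1, p) == 1, "DVT_HOSP", "DVT_COMM"),
    age_ge_60 = age_flag, cancer = cancer,
    noise_flag = rbinom(n, 1, 0.3) == 1)
  spec <- model_spec("HOSPITAL_SETTING_BINARY",
                     c("age_ge_60", "cancer", "noise_flag"))
  res <- two_step_procedure(cohort, spec)
  expect_true(all(c("age_ge_60", "cancer") %in% res$retained))
  expect_true(all(res$terms[res$terms$term %in%
                              c("age_ge_60TRUE", "cancerTRUE"), ]$ratio > 1))
})
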
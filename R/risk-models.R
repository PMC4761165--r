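## Two-step risk-factor modelling: each candidate covariate is screened in
## a univariate model at screen_alpha; survivors enter one multivariate
## model — Cox proportional hazards (Breslow ties) for time to recurrence,
## logistic for hospital vs community management of DVT.

#' Specification of a two-step risk-factor model
#'
#' @param outcome `"RECURRENCE_TIME_TO_EVENT"` (Cox on days to first
#'   recurrence, deaths and end of follow-up censoring) or
#'   `"HOSPITAL_SETTING_BINARY"` (logistic on hospital vs community
#'   management, DVT patients only).
#' @param candidates character vector of cohort flag columns to screen.
#' @param screen_alpha univariate retention threshold (default 0.05).
#' @param final_alpha significance level reported for the multivariate
#'   model (default 0.05).
#' @param ties tie handling for the Cox partial likelihood (`"breslow"`
#'   default, `"efron"` available).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("RECURRENCE_TIME_TO_EVENT",
                                   "HOSPITAL_SETTING_BINARY"),
                       candidates,
                       screen_alpha = 0.05, final_alpha = 0.05,
                       ties = c("breslow", "efron")) {
  outcome <- match.arg(outcome)
  ties <- match.arg(ties)
  if (screen_alpha <= 0 || screen_alpha >= 1 ||
      final_alpha <= 0 || final_alpha >= 1)
    stop("alpha levels must lie in (0, 1)")
  if (missing(candidates) || length(candidates) == 0L)
    candidates <- character(0)
  structure(list(outcome = outcome, candidates = candidates,
                 screen_alpha = screen_alpha, final_alpha = final_alpha,
                 ties = ties), class = "model_spec")
}

model_frame <- function(cohort, spec) {
  cohort <- as.data.table(cohort)
  if (spec$outcome == "HOSPITAL_SETTING_BINARY") {
    d <- cohort[index_category %in% c("DVT_HOSP", "DVT_COMM")]
    d$.y <- as.integer(d$index_category == "DVT_HOSP")
  } else {
    d <- copy(cohort)
    if (!all(c("time_to_event", "event_status") %in% names(d)))
      stop("cohort lacks time_to_event/event_status; run detect_recurrences first")
    ## subjects must contribute positive time to the partial likelihood
    d <- d[time_to_event > 0]
  }
  d
}

term_table <- function(coefs, ses, n, converged) {
  z <- coefs / ses
  out <- data.frame(term = names(coefs), estimate = unname(coefs),
                    ratio = exp(unname(coefs)),
                    ci_low = exp(unname(coefs - 1.96 * ses)),
                    ci_high = exp(unname(coefs + 1.96 * ses)),
                    p = 2 * pnorm(-abs(unname(z))))
  structure(list(terms = out, converged = converged, n = n),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result> n =", x$n,
      if (!x$converged) "(NOT converged)" else "", "\n")
  if (nrow(x$terms) == 0L) cat("  (empty model)\n") else
    print(format(x$terms, digits = 3), row.names = FALSE)
  invisible(x)
}

univariate_p <- function(d, covariate, spec) {
  x <- d[[covariate]]
  if (length(unique(x[!is.na(x)])) < 2L) return(NA_real_)
  if (spec$outcome == "HOSPITAL_SETTING_BINARY") {
    fit <- glm(d$.y ~ x, family = binomial())
    summary(fit)$coefficients[2, 4]
  } else {
    ## rare flags with no event in one arm push the coefficient to infinity;
    ## the Wald p then approaches 1 and the screen drops the covariate, so
    ## the convergence warning carries no information here
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(d$time_to_event, d$event_status) ~ x,
                      ties = spec$ties),
      warning = function(w) {
        if (grepl("coefficient may be infinite", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    summary(fit)$coefficients[1, 5]
  }
}

#' Univariate screening of candidate covariates
#'
#' Each candidate is tested alone against the outcome; those with p below
#' `screen_alpha` are retained, in input order. Zero-variance covariates
#' are dropped with a message.
#'
#' @param cohort analysis cohort; @param spec a [model_spec()].
#' @return character vector of retained covariate names, with attribute
#'   `p_values` (named, all screened candidates).
#' @export
screen_univariate <- function(cohort, spec) {
  d <- model_frame(cohort, spec)
  miss <- setdiff(spec$candidates, names(d))
  if (length(miss) > 0L)
    stop("candidate covariate(s) absent from cohort: ",
         paste(miss, collapse = ", "))
  ps <- vapply(spec$candidates, function(v)
    tryCatch(univariate_p(d, v, spec), error = function(e) NA_real_),
    numeric(1))
  dropped <- names(ps)[is.na(ps)]
  if (length(dropped) > 0L)
    message("dropped zero-variance/unfittable covariate(s): ",
            paste(dropped, collapse = ", "))
  retained <- names(ps)[!is.na(ps) & ps < spec$screen_alpha]
  attr(retained, "p_values") <- ps
  retained
}

#' Multivariate Cox proportional-hazards model for recurrence
#'
#' Partial-likelihood fit (Breslow ties by default) of days to first
#' recurrence, deaths and end of follow-up censoring, on the given
#' covariates; hazard ratios with Wald CIs and p-values.
#'
#' @param cohort analysis cohort with `time_to_event`/`event_status`.
#' @param covariates covariate column names.
#' @param ties `"breslow"` or `"efron"`.
#' @return a `model_result`.
#' @export
fit_cox_model <- function(cohort, covariates, ties = "breslow") {
  d <- model_frame(cohort, model_spec("RECURRENCE_TIME_TO_EVENT",
                                      covariates, ties = ties))
  if (length(covariates) == 0L)
    return(term_table(setNames(numeric(0), character(0)), numeric(0),
                      nrow(d), TRUE))
  f <- as.formula(paste("survival::Surv(time_to_event, event_status) ~",
                        paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = ties)
  conv <- is.null(fit$info) && !any(is.na(coef(fit)))
  if (any(is.na(coef(fit))))
    stop("Cox fit produced undefined coefficients (collinear covariates?)")
  if (any(abs(coef(fit)) > 15))
    stop("Cox fit diverged (likely complete separation)")
  res <- term_table(coef(fit), sqrt(diag(vcov(fit))), fit$n, TRUE)
  res$fit <- fit
  res
}

#' Multivariate logistic model for hospitalisation of DVT
#'
#' Maximum-likelihood logistic regression (IRLS via `glm`) of hospital vs
#' community management among DVT patients; odds ratios with Wald CIs.
#'
#' @param cohort analysis cohort; @param covariates covariate column names.
#' @return a `model_result`.
#' @export
fit_logistic_model <- function(cohort, covariates) {
  d <- model_frame(cohort, model_spec("HOSPITAL_SETTING_BINARY", covariates))
  if (nrow(d) == 0L) stop("no DVT patients in cohort")
  if (length(covariates) == 0L) {
    fit <- glm(.y ~ 1, data = d, family = binomial())
    return(term_table(coef(fit), sqrt(diag(vcov(fit))), nrow(d),
                      fit$converged))
  }
  f <- as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warn || any(abs(coef(fit)[-1]) > 15))
    stop("logistic fit separated: a covariate perfectly predicts the outcome")
  res <- term_table(coef(fit)[-1], sqrt(diag(vcov(fit)))[-1], nrow(d),
                    fit$converged)
  res$fit <- fit
  res
}

#' Two-step procedure: univariate screen then multivariate fit
#'
#' Covariates passing the univariate screen at `screen_alpha` enter a
#' single multivariate model (no further stepwise iteration). If none
#' passes, an empty model is returned with a notice.
#'
#' @param cohort analysis cohort; @param spec a [model_spec()].
#' @return a `model_result` with attributes `retained` (screen survivors)
#'   and `screen_p` (univariate p-values).
#' @export
two_step_procedure <- function(cohort, spec) {
  retained <- screen_univariate(cohort, spec)
  res <- if (length(retained) == 0L) {
    r <- term_table(setNames(numeric(0), character(0)), numeric(0),
                    nrow(model_frame(cohort, spec)), TRUE)
    r$notice <- "no covariate passed the univariate screen"
    r
  } else if (spec$outcome == "RECURRENCE_TIME_TO_EVENT") {
    fit_cox_model(cohort, retained, ties = spec$ties)
  } else {
    fit_logistic_model(cohort, retained)
  }
  res$retained <- as.character(retained)
  res$screen_p <- attr(retained, "p_values")
  res
}
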
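## Independent oracles used to cross-check package implementations on tiny
## inputs. These deliberately share no code with the package.

## Fisher exact r x c by brute-force enumeration of all tables with the
## observed margins; two-sided p = sum of probabilities of tables no more
## probable than the observed one.
enumerate_tables <- function(row_margins, col_margins) {
  r <- length(row_margins); c <- length(col_margins)
  out <- list()
  recurse <- function(filled, row_left, col_left, i, j) {
    if (i > r) {
      if (all(col_left == 0)) out[[length(out) + 1L]] <<- filled
      return(invisible(NULL))
    }
    if (j == c) {
      v <- row_left[i]
      if (v <= col_left[c]) {
        f2 <- filled; f2[i, c] <- v
        cl <- col_left; cl[c] <- cl[c] - v
        rl <- row_left; rl[i] <- 0L
        recurse(f2, rl, cl, i + 1L, 1L)
      }
      return(invisible(NULL))
    }
    for (v in 0:min(row_left[i], col_left[j])) {
      f2 <- filled; f2[i, j] <- v
      cl <- col_left; cl[j] <- cl[j] - v
      rl <- row_left; rl[i] <- rl[i] - v
      recurse(f2, rl, cl, i, j + 1L)
    }
  }
  recurse(matrix(0L, r, c), row_margins, col_margins, 1L, 1L)
  out
}

## hypergeometric probability of a table given its margins
table_log_prob <- function(tab) {
  rm <- rowSums(tab); cm <- colSums(tab); n <- sum(tab)
  sum(lfactorial(rm)) + sum(lfactorial(cm)) - lfactorial(n) -
    sum(lfactorial(tab))
}

fisher_oracle <- function(tab) {
  tabs <- enumerate_tables(rowSums(tab), colSums(tab))
  lps <- vapply(tabs, table_log_prob, numeric(1))
  lp0 <- table_log_prob(tab)
  sum(exp(lps[lps <= lp0 + 1e-9] - 0))
}

## hand product-limit estimator (no ties handling subtleties at this size)
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

## brute-force Cox partial likelihood (Breslow) over a beta grid
cox_loglik_breslow <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    d <- which(time == t & status == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

cox_grid_oracle <- function(time, status, x,
                            grid = seq(-4, 4, by = 0.001)) {
  lls <- vapply(grid, cox_loglik_breslow, numeric(1),
                time = time, status = status, x = x)
  grid[which.max(lls)]
}

## tiny deterministic dataset builders --------------------------------------

make_persons <- function(n, birth = "1960-01-01") {
  data.frame(person_id = sprintf("P%03d", seq_len(n)), sex = "F",
             birth_date = as.Date(birth), death_date = as.Date(NA),
             coverage_start = as.Date("2008-01-01"),
             coverage_end = as.Date("2013-12-31"))
}

make_claims <- function(person, days, classes,
                        base = as.Date("2010-01-01")) {
  data.frame(person_id = person, service_date = base + days,
             service_class = classes, prescriber = "GP")
}

make_stays <- function(person, adm_days, primary, associated = "",
                       los = 5L, base = as.Date("2010-01-01")) {
  data.frame(person_id = person, admission_date = base + adm_days,
             discharge_date = base + adm_days + los,
             primary_dx = primary, associated_dx = associated)
}

empty_claims <- function()
  data.frame(person_id = character(0), service_date = as.Date(character(0)),
             service_class = character(0), prescriber = character(0))
empty_stays <- function()
  data.frame(person_id = character(0), admission_date = as.Date(character(0)),
             discharge_date = as.Date(character(0)),
             primary_dx = character(0), associated_dx = character(0))

small_dataset <- function(persons, claims = empty_claims(),
                          stays = empty_stays()) {
  claims_dataset(persons, claims, stays)
}
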
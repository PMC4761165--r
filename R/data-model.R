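## The three claims tables and their validation.
##
## persons : person_id, sex (F/M), birth_date, death_date (may be empty),
##           coverage_start, coverage_end
## claims  : person_id, service_date, service_class, prescriber
##           (per-event community reimbursements; no diagnosis attached)
## stays   : person_id, admission_date, discharge_date, primary_dx,
##           associated_dx (";"-separated ICD-10 codes, may be empty)

SERVICE_CLASSES <- c("ECHO_DOPPLER", "LMWH", "FONDAPARINUX", "VKA",
                     "HORMONAL_THERAPY", "OTHER")
PRESCRIBERS <- c("GP", "SPECIALIST", "HOSPITAL", "UNKNOWN")
DX_SEP <- ";"

#' Completed age in years at a date
#'
#' @param birth_date,date `Date` vectors (recycled).
#' @return integer vector of completed years.
#' @examples
#' age_at(as.Date("1950-06-15"), as.Date("2010-06-15"))  # 60
#' @export
age_at <- function(birth_date, date) {
  birth_date <- as.Date(birth_date); date <- as.Date(date)
  if (any(date < birth_date, na.rm = TRUE))
    stop("age_at: date precedes birth_date")
  by <- as.integer(format(birth_date, "%Y"))
  dy <- as.integer(format(date, "%Y"))
  bmd <- as.integer(format(birth_date, "%m")) * 100L +
    as.integer(format(birth_date, "%d"))
  dmd <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  dy - by - as.integer(dmd < bmd)
}

parse_date_col <- function(x, col, file) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & x != "" & is.na(d))
  if (length(bad) > 0L)
    stop("unparseable date in ", file, ", column '", col, "', row(s) ",
         paste(head(bad, 5L), collapse = ", "),
         " (value '", as.character(x[bad[1]]), "')")
  d
}

#' Assemble and validate a claims dataset from in-memory tables
#'
#' Checks types, enum membership, date ordering, ICD-10 code syntax, and
#' referential integrity (every claim and stay must join to exactly one
#' person). Orphan rows are a validation error reporting the count.
#'
#' @param persons,claims,stays data.frames with the documented columns.
#' @return object of class `claims_dataset`: list of three data.tables.
#' @export
claims_dataset <- function(persons, claims, stays) {
  persons <- as.data.table(persons); claims <- as.data.table(claims)
  stays <- as.data.table(stays)

  need <- function(dt, cols, what) {
    miss <- setdiff(cols, names(dt))
    if (length(miss) > 0L)
      stop(what, " table missing column(s): ", paste(miss, collapse = ", "))
  }
  need(persons, c("person_id", "sex", "birth_date", "death_date",
                  "coverage_start", "coverage_end"), "persons")
  need(claims, c("person_id", "service_date", "service_class", "prescriber"),
       "claims")
  need(stays, c("person_id", "admission_date", "discharge_date",
                "primary_dx", "associated_dx"), "stays")

  for (col in c("birth_date", "death_date", "coverage_start", "coverage_end"))
    persons[[col]] <- as.Date(persons[[col]])
  claims[, service_date := as.Date(service_date)]
  stays[, admission_date := as.Date(admission_date)]
  stays[, discharge_date := as.Date(discharge_date)]
  persons[, person_id := as.character(person_id)]
  claims[, person_id := as.character(person_id)]
  stays[, person_id := as.character(person_id)]
  stays[, primary_dx := as.character(primary_dx)]
  stays[, associated_dx := {
    a <- as.character(associated_dx); a[is.na(a)] <- ""; a
  }]

  if (anyDuplicated(persons$person_id))
    stop("duplicate person_id in persons table")
  if (any(!is.na(persons$death_date) & persons$birth_date >= persons$death_date))
    stop("persons with birth_date >= death_date")
  if (any(persons$coverage_start > persons$coverage_end))
    stop("persons with coverage_start > coverage_end")
  if (any(!persons$sex %in% c("F", "M")))
    stop("persons.sex must be 'F' or 'M'")

  bad_class <- setdiff(unique(claims$service_class), SERVICE_CLASSES)
  if (length(bad_class) > 0L)
    stop("unknown service_class token(s): ", paste(bad_class, collapse = ", "))
  bad_presc <- setdiff(unique(claims$prescriber), PRESCRIBERS)
  if (length(bad_presc) > 0L)
    stop("unknown prescriber token(s): ", paste(bad_presc, collapse = ", "))

  if (any(stays$admission_date > stays$discharge_date))
    stop("stays with admission_date > discharge_date")
  all_dx <- c(stays$primary_dx,
              unlist(strsplit(stays$associated_dx[stays$associated_dx != ""],
                              DX_SEP, fixed = TRUE)))
  all_dx <- trimws(all_dx)
  bad_dx <- unique(all_dx[!grepl(ICD10_CODE_RE, all_dx)])
  if (length(bad_dx) > 0L)
    stop("malformed ICD-10 code(s) on stays: ",
         paste(head(bad_dx, 5L), collapse = ", "))

  orphan_claims <- sum(!claims$person_id %in% persons$person_id)
  orphan_stays  <- sum(!stays$person_id %in% persons$person_id)
  if (orphan_claims + orphan_stays > 0L)
    stop("referential integrity failure: ", orphan_claims,
         " claim row(s) and ", orphan_stays,
         " stay row(s) reference unknown person_id")

  setkey(persons, person_id)
  setkey(claims, person_id, service_date)
  setkey(stays, person_id, admission_date)
  structure(list(persons = persons, claims = claims, stays = stays),
            class = "claims_dataset")
}

#' Read a validated claims dataset from three delimited files
#'
#' Files are comma-separated with a header row; dates in ISO `YYYY-MM-DD`
#' format; an empty `death_date` means alive. Any validation failure
#' (unparseable date, unknown enum token, orphan row) is an error naming
#' the offending file/row.
#'
#' @param persons_path,claims_path,stays_path CSV file paths.
#' @return a `claims_dataset`.
#' @export
read_claims_dataset <- function(persons_path, claims_path, stays_path) {
  for (p in c(persons_path, claims_path, stays_path))
    if (!file.exists(p)) stop("file not found: ", p)
  persons <- fread(persons_path, colClasses = "character", na.strings = NULL)
  claims <- fread(claims_path, colClasses = "character", na.strings = NULL)
  stays <- fread(stays_path, colClasses = "character", na.strings = NULL)

  for (col in c("birth_date", "death_date", "coverage_start", "coverage_end"))
    if (col %in% names(persons))
      persons[[col]] <- parse_date_col(persons[[col]], col, persons_path)
  if ("service_date" %in% names(claims))
    claims$service_date <- parse_date_col(claims$service_date, "service_date",
                                          claims_path)
  for (col in c("admission_date", "discharge_date"))
    if (col %in% names(stays))
      stays[[col]] <- parse_date_col(stays[[col]], col, stays_path)
  claims_dataset(persons, claims, stays)
}

#' Write a claims dataset to three CSV files
#'
#' Emits `persons.csv`, `claims.csv`, `stays.csv` under `dir`; the
#' round-trip through [read_claims_dataset()] is lossless. Internal
#' bookkeeping columns (e.g. the generator's claim origin) are dropped.
#'
#' @param dataset a `claims_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_claims_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "claims_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("persons.csv", "claims.csv", "stays.csv"))
  keep <- list(
    persons = c("person_id", "sex", "birth_date", "death_date",
                "coverage_start", "coverage_end"),
    claims = c("person_id", "service_date", "service_class", "prescriber"),
    stays = c("person_id", "admission_date", "discharge_date",
              "primary_dx", "associated_dx"))
  fwrite(dataset$persons[, keep$persons, with = FALSE], paths[1])
  fwrite(dataset$claims[, keep$claims, with = FALSE], paths[2])
  fwrite(dataset$stays[, keep$stays, with = FALSE], paths[3])
  invisible(setNames(paths, c("persons", "claims", "stays")))
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset> ", nrow(x$persons), " persons, ",
      nrow(x$claims), " community claims, ", nrow(x$stays),
      " hospital stays\n", sep = "")
  invisible(x)
}

split_dx <- function(associated_dx) {
  strsplit(ifelse(is.na(associated_dx), "", associated_dx), DX_SEP,
           fixed = TRUE)
}

## TRUE where any of the stay's codes (primary or associated) is in `codes`
stay_matches <- function(stays, codes) {
  prim <- stays$primary_dx %in% codes
  assoc <- vapply(split_dx(stays$associated_dx),
                  function(v) any(trimws(v) %in% codes), logical(1))
  list(primary = prim, associated = assoc)
}
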
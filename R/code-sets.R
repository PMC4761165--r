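## ICD-10 code sets used to capture VTE diagnoses on hospital stays.
## Codes are letter + two digits + optional one-digit subcode ("I80.3").
## Range tokens like "I80.1-9" expand to the enumerated subcodes; matching
## downstream is exact on the expanded set (no prefix matching).

ICD10_CODE_RE  <- "^[A-Z][0-9]{2}(\\.[0-9])?$"
ICD10_RANGE_RE <- "^([A-Z][0-9]{2})\\.([0-9])-([0-9])$"

#' Expand ICD-10 range tokens into explicit codes
#'
#' A token is either a plain ICD-10 code (`"I26.0"`, `"O80"`) or a subcode
#' range such as `"I80.1-9"`, which expands to `I80.1`, `I80.2`, ...,
#' `I80.9`. Expansion is idempotent: an already-expanded vector is returned
#' unchanged (sorted, deduplicated).
#'
#' @param tokens character vector of codes and/or range tokens.
#' @return character vector of explicit, validated ICD-10 codes.
#' @examples
#' expand_icd10_ranges(c("I80.1-9", "I26.0"))
#' @export
expand_icd10_ranges <- function(tokens) {
  stopifnot(is.character(tokens))
  out <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec(ICD10_RANGE_RE, tok))[[1]]
    if (length(m) == 4L) {
      lo <- as.integer(m[3]); hi <- as.integer(m[4])
      if (lo > hi) stop("invalid ICD-10 range token (descending): ", tok)
      paste0(m[2], ".", seq(lo, hi))
    } else if (grepl(ICD10_CODE_RE, tok)) {
      tok
    } else {
      stop("malformed ICD-10 code or range token: '", tok, "'")
    }
  })
  sort(unique(unlist(out)))
}

#' Construct the VTE diagnosis code set
#'
#' Defaults are the codes under which VTE is recorded in discharge data:
#' `I80.1-9` and `I82.1-9` (DVT) and `I26.0`, `I26.9` (PE). Range tokens
#' are expanded; the two sets must be disjoint and non-empty.
#'
#' @param dvt_codes,pe_codes character vectors of codes/range tokens.
#' @return object of class `vte_code_set`: list with `dvt_codes`, `pe_codes`.
#' @export
vte_code_set <- function(dvt_codes = c("I80.1-9", "I82.1-9"),
                         pe_codes  = c("I26.0", "I26.9")) {
  dvt <- expand_icd10_ranges(dvt_codes)
  pe  <- expand_icd10_ranges(pe_codes)
  if (length(dvt) == 0L) stop("empty mandatory code set: dvt_codes")
  if (length(pe)  == 0L) stop("empty mandatory code set: pe_codes")
  overlap <- intersect(dvt, pe)
  if (length(overlap) > 0L)
    stop("dvt_codes and pe_codes overlap: ", paste(overlap, collapse = ", "))
  structure(list(dvt_codes = dvt, pe_codes = pe), class = "vte_code_set")
}

#' Load a VTE code set from a YAML/JSON config file
#'
#' The file may define `dvt_codes` and `pe_codes` (each a list of codes or
#' range tokens). An absent path returns the defaults of [vte_code_set()].
#'
#' @param path path to a YAML or JSON file, or `NULL` for defaults.
#' @return a `vte_code_set`.
#' @export
load_code_set <- function(path = NULL) {
  if (is.null(path)) return(vte_code_set())
  if (!file.exists(path)) stop("code set file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$dvt_codes) && is.null(cfg$pe_codes))
    stop("code set file defines neither 'dvt_codes' nor 'pe_codes': ", path)
  args <- list()
  if (!is.null(cfg$dvt_codes)) args$dvt_codes <- unlist(cfg$dvt_codes)
  if (!is.null(cfg$pe_codes))  args$pe_codes  <- unlist(cfg$pe_codes)
  if (!is.null(cfg$pe_codes) && length(unlist(cfg$pe_codes)) == 0L)
    stop("empty mandatory code set: pe_codes")
  if (!is.null(cfg$dvt_codes) && length(unlist(cfg$dvt_codes)) == 0L)
    stop("empty mandatory code set: dvt_codes")
  do.call(vte_code_set, args)
}

#' @export
print.vte_code_set <- function(x, ...) {
  cat("<vte_code_set>\n")
  cat("  DVT:", paste(x$dvt_codes, collapse = " "), "\n")
  cat("  PE: ", paste(x$pe_codes, collapse = " "), "\n")
  invisible(x)
}
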
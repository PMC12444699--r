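#' An admission-level diagnosis record
#'
#' One inpatient admission with its primary ICD-10-CM code, any secondary
#' codes, whether an acute-exacerbation / status-asthmaticus code is
#' present, and any cohort exclusion conditions.
#'
#' @param primary_code primary ICD-10-CM code (letter + digits, optional
#'   dotted suffix, e.g. `"J45.901"`).
#' @param secondary_codes character vector of secondary codes (may be
#'   empty).
#' @param has_exacerbation_or_status does the record carry an acute
#'   exacerbation or status asthmaticus code?
#' @param exclusion_flags subset of
#'   `c("cystic_fibrosis", "congenital_heart_disease",
#'   "chronic_respiratory_failure", "sickle_cell", "tracheostomy",
#'   "ventilator_dependent")`.
#' @param date optional admission date (used by
#'   [aggregate_records_to_series()]).
#' @return an object of class `admission_record`.
#' @export
admission_record <- function(primary_code, secondary_codes = character(0),
                             has_exacerbation_or_status = FALSE,
                             exclusion_flags = character(0), date = NULL) {
  known <- c("cystic_fibrosis", "congenital_heart_disease",
             "chronic_respiratory_failure", "sickle_cell", "tracheostomy",
             "ventilator_dependent")
  check_icd <- function(code) {
    if (!grepl("^[A-Z][0-9][0-9A-Z]*(\\.[0-9A-Z]+)?$", code))
      stop("malformed ICD-10-CM code: ", code)
  }
  check_icd(primary_code)
  for (code in secondary_codes) check_icd(code)
  bad <- setdiff(exclusion_flags, known)
  if (length(bad)) stop("unknown exclusion flag(s): ", paste(bad, collapse = ", "))
  structure(list(primary_code = primary_code,
                 secondary_codes = as.character(secondary_codes),
                 has_exacerbation_or_status = isTRUE(has_exacerbation_or_status),
                 exclusion_flags = exclusion_flags,
                 date = if (!is.null(date)) as.Date(date)),
            class = "admission_record")
}

#' Default respiratory primary-diagnosis prefixes
#'
#' The cohort rule admits a record with a non-asthma primary diagnosis when
#' the primary is a respiratory infection, cough, non-chronic respiratory
#' failure, shortness of breath, or hypoxemia and a secondary J45 code is
#' present. The exact institutional code lists behind those category names
#' are not public, so this default is an explicit, documented approximation
#' by ICD-10-CM prefix: acute respiratory infections (J00-J06, J09-J18,
#' J20-J22), cough (R05), acute respiratory failure (J96.0), shortness of
#' breath (R06.0), and hypoxemia (R09.02). Pass your own prefix vector to
#' [classify_admission()] to match an institutional definition.
#'
#' @return character vector of code prefixes.
#' @export
default_respiratory_prefixes <- function() {
  c("J0", "J1", "J20", "J21", "J22",   # acute respiratory infections
    "R05",                             # cough
    "J96.0",                           # acute (non-chronic) respiratory failure
    "R06.0",                           # shortness of breath / dyspnea
    "R09.02")                          # hypoxemia
}

code_has_prefix <- function(code, prefixes) {
  any(vapply(prefixes, function(p) startsWith(code, p), TRUE))
}

#' Classify a record as a countable asthma admission
#'
#' A record counts as an asthma hospitalization when (a) the primary
#' diagnosis is a J45 asthma code, or the primary is in the respiratory
#' primary set and some secondary code is J45; and (b) an acute
#' exacerbation or status asthmaticus code is present; and (c) no exclusion
#' condition (cystic fibrosis, congenital heart disease, chronic
#' respiratory failure, sickle cell disease, tracheostomy, ventilator
#' dependence) applies.
#'
#' @param record an [admission_record()].
#' @param respiratory_primary_set code-prefix vector for the secondary-J45
#'   pathway; default [default_respiratory_prefixes()].
#' @return `TRUE` or `FALSE`.
#' @export
classify_admission <- function(record,
                               respiratory_primary_set = default_respiratory_prefixes()) {
  stopifnot(inherits(record, "admission_record"))
  primary_asthma <- startsWith(record$primary_code, "J45")
  secondary_asthma <- any(startsWith(record$secondary_codes, "J45"))
  respiratory_primary <- code_has_prefix(record$primary_code, respiratory_primary_set)
  diagnosis_ok <- primary_asthma || (respiratory_primary && secondary_asthma)
  diagnosis_ok && record$has_exacerbation_or_status &&
    length(record$exclusion_flags) == 0L
}

#' Aggregate admission records into a daily count series
#'
#' Counts, for every calendar day in `[start, end]`, the records dated that
#' day that [classify_admission()] accepts; days with no qualifying record
#' get count zero.
#'
#' @param records list of dated [admission_record()]s.
#' @param start,end series date range (must contain all record dates).
#' @param respiratory_primary_set passed to [classify_admission()].
#' @return an `adm_series`.
#' @export
aggregate_records_to_series <- function(records, start, end,
                                        respiratory_primary_set =
                                          default_respiratory_prefixes()) {
  start <- as.Date(start); end <- as.Date(end)
  dates <- seq(start, end, by = "day")
  counts <- setNames(integer(length(dates)), format(dates))
  for (rec in records) {
    stopifnot(inherits(rec, "admission_record"))
    if (is.null(rec$date)) stop("record without a date cannot be aggregated")
    if (rec$date < start || rec$date > end)
      stop("record dated ", format(rec$date), " outside [", format(start),
           ", ", format(end), "]")
    if (classify_admission(rec, respiratory_primary_set)) {
      key <- format(rec$date)
      counts[[key]] <- counts[[key]] + 1L
    }
  }
  daily_series(dates, unname(counts))
}
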
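#' Confirmed-diagnosis rule
#'
#' A type 1 diabetes diagnosis counts as confirmed in the lookback year if it
#' appears at least twice in different calendar quarters in the outpatient
#' setting, or at least once in the inpatient setting.
#'
#' @param records data.frame of diagnosis records (`date`, `setting`) for one
#'   patient.
#' @param year lookback calendar year.
#' @return logical.
#' @export
confirm_diagnosis <- function(records, year) {
  if (!nrow(records)) return(FALSE)
  d <- as_date_strict(records$date, "diagnosis date")
  in_year <- date_year(d) == year
  if (any(in_year & records$setting == "inpatient")) return(TRUE)
  out <- in_year & records$setting == "outpatient"
  length(unique(date_quarter(d[out]))) >= 2L
}

#' Birth-year eligibility
#'
#' Patients aged 11 to 14 in the first observation year, i.e. birth years
#' 2003-2006 under the default window.
#'
#' @param birth_year integer vector.
#' @param range inclusive `c(min, max)` birth-year window.
#' @return logical vector.
#' @export
age_filter <- function(birth_year, range = c(2003L, 2006L)) {
  if (anyNA(birth_year)) stop("missing birth_year", call. = FALSE)
  birth_year >= range[1] & birth_year <= range[2]
}

#' Continuous-insurance check
#'
#' Coverage intervals (string format `"start/end;start/end"`) must jointly
#' span the required period with no gap of one day or more.
#'
#' @param coverage character vector of coverage strings, one per patient.
#' @param from,to required span (ISO dates), default 2016-01-01..2019-12-31.
#' @return logical vector.
#' @export
is_continuously_insured <- function(coverage, from = "2016-01-01",
                                    to = "2019-12-31") {
  from <- as_date_strict(from); to <- as_date_strict(to)
  vapply(coverage, function(cv) {
    if (is.na(cv) || !nzchar(cv)) return(FALSE)
    parts <- strsplit(strsplit(cv, ";", fixed = TRUE)[[1]], "/", fixed = TRUE)
    iv <- do.call(rbind, lapply(parts, function(p)
      data.frame(start = as_date_strict(p[1], "coverage"),
                 end = as_date_strict(p[2], "coverage"))))
    iv <- iv[order(iv$start), , drop = FALSE]
    if (iv$start[1] > from) return(FALSE)
    reach <- iv$end[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] > reach + 1L) break  # gap >= 1 day
      reach <- max(reach, iv$end[i])
    }
    reach >= to
  }, logical(1), USE.NAMES = FALSE)
}

#' Hospital-outpatient exclusion rule
#'
#' A patient is classified as a hospital outpatient when events billed in the
#' hospital-outpatient setting occur in at least `min_quarters` distinct
#' calendar quarters of the observation window (default 8 of 12).
#'
#' @param events data.frame of event records for one patient.
#' @param window observation window `c(start, end)`, end inclusive.
#' @param min_quarters threshold on distinct quarters.
#' @return logical.
#' @export
flag_hospital_outpatient <- function(events, window = c("2017-01-01", "2019-12-31"),
                                     min_quarters = 8L) {
  if (!nrow(events)) return(FALSE)
  sel <- events$setting == "hospital_outpatient"
  if (!any(sel)) return(FALSE)
  d <- as_date_strict(events$date[sel], "event date")
  w <- as_date_strict(window)
  d <- d[d >= w[1] & d <= w[2]]
  length(unique(year_quarter(d))) >= min_quarters
}

#' Apply the inclusion and exclusion rules to the raw tables
#'
#' Rules, in reporting order: confirmed diagnosis in the lookback year,
#' birth-year eligibility, continuous insurance over the full data period,
#' and absence of routine hospital-outpatient care. Inclusion is the
#' conjunction of all four flags, so the final cohort does not depend on the
#' order; the attrition log attributes each excluded patient to the first
#' failing rule.
#'
#' @param tables list with `patients`, `diagnoses`, `events` (as produced by
#'   [generate_cohort()] or [read_fixture()]).
#' @param lookback_year diagnosis-confirmation year.
#' @param birth_year_range inclusive birth-year window.
#' @param coverage_span required insurance span `c(from, to)`.
#' @param window observation window for the hospital-outpatient rule.
#' @param min_ho_quarters hospital-outpatient quarter threshold.
#' @return list with `cohort` (included patients), `flags` (per-patient flag
#'   audit) and `attrition` (per-rule removal counts).
#' @export
select_cohort <- function(tables,
                          lookback_year = 2016L,
                          birth_year_range = c(2003L, 2006L),
                          coverage_span = c("2016-01-01", "2019-12-31"),
                          window = c("2017-01-01", "2019-12-31"),
                          min_ho_quarters = 8L) {
  patients <- tables$patients
  need <- c("patient_id", "birth_year", "coverage")
  missing_cols <- setdiff(need, names(patients))
  if (length(missing_cols))
    stop(sprintf("patients table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (tb in c("diagnoses", "events")) {
    if (!all(c("patient_id", "date", "setting") %in% names(tables[[tb]])))
      stop(sprintf("%s table lacks required columns", tb), call. = FALSE)
  }
  ids <- patients$patient_id

  dx_by <- split(tables$diagnoses, tables$diagnoses$patient_id)
  confirmed <- vapply(ids, function(id) {
    rec <- dx_by[[id]]
    !is.null(rec) && confirm_diagnosis(rec, lookback_year)
  }, logical(1), USE.NAMES = FALSE)

  age_ok <- age_filter(patients$birth_year, birth_year_range)
  insured <- is_continuously_insured(patients$coverage,
                                     coverage_span[1], coverage_span[2])

  # distinct hospital-outpatient quarters, vectorized over the event table
  ev <- tables$events
  sel <- ev$setting == "hospital_outpatient"
  ho <- rep(FALSE, length(ids))
  if (any(sel)) {
    d <- as_date_strict(ev$date[sel], "event date")
    w <- as_date_strict(window)
    inw <- d >= w[1] & d <= w[2]
    key <- paste(ev$patient_id[sel][inw], year_quarter(d[inw]))
    nq <- table(sub(" .*", "", unique(key)))
    ho[match(names(nq)[nq >= min_ho_quarters], ids)] <- TRUE
  }

  included <- confirmed & age_ok & insured & !ho
  flags <- data.frame(patient_id = ids, confirmed_dx = confirmed,
                      age_eligible = age_ok, continuously_insured = insured,
                      hospital_outpatient = ho, included = included,
                      stringsAsFactors = FALSE)

  # first-failing-rule attribution, in the stated order
  fail1 <- !confirmed
  fail2 <- confirmed & !age_ok
  fail3 <- confirmed & age_ok & !insured
  fail4 <- confirmed & age_ok & insured & ho
  attrition <- list(
    n_input = length(ids),
    removed = c(no_confirmed_diagnosis = sum(fail1),
                age_ineligible = sum(fail2),
                not_continuously_insured = sum(fail3),
                hospital_outpatient = sum(fail4)),
    n_included = sum(included))

  list(cohort = patients[included, , drop = FALSE],
       flags = flags, attrition = attrition)
}
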
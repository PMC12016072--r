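#' State alphabets of the three care dimensions
#'
#' The pipeline tracks six binary events grouped into three dimensions:
#' * `hcp_contact` (quarterly): outpatient contact -> states `N`, `O`;
#' * `diagnostics` (quarterly): HbA1c measurement (`H`) and a quarterly
#'   test-strip supply of at least 200 units (`B`) -> states `N`, `H`, `B`,
#'   `HB`;
#' * `screening` (annual): retinopathy (`R`), cholesterol (`C`) and thyroid
#'   (`T`) screening -> the 8 presence combinations `N`, `R`, `C`, `T`, `RC`,
#'   `RT`, `CT`, `RCT` (letters in fixed order R, C, T; `N` = none).
#'
#' @param dimension one of `"hcp_contact"`, `"diagnostics"`, `"screening"`.
#' @return list with `dimension`, `granularity`, the underlying `events`, and
#'   the canonical `states` vector (length 2, 4 or 8).
#' @export
state_alphabet <- function(dimension = DIMENSIONS) {
  dimension <- match.arg(dimension)
  switch(dimension,
    hcp_contact = list(
      dimension = "hcp_contact", granularity = "quarter",
      events = "OUTPATIENT_CONTACT",
      states = c("N", "O")),
    diagnostics = list(
      dimension = "diagnostics", granularity = "quarter",
      events = c("HBA1C", "STRIPS_RX"),
      states = c("N", "H", "B", "HB")),
    screening = list(
      dimension = "screening", granularity = "year",
      events = c("RETINOPATHY_SCREEN", "CHOLESTEROL_SCREEN", "THYROID_SCREEN"),
      states = c("N", "R", "C", "T", "RC", "RT", "CT", "RCT")))
}

#' Build the interval timeline of the observation window
#'
#' Splits the window into half-open calendar intervals `[start, end)`:
#' quarters (Jan-Mar, Apr-Jun, Jul-Sep, Oct-Dec) or calendar years. The
#' window must be aligned: `start` on a quarter (or year) boundary and `end`
#' the last day of a quarter (or year).
#'
#' @param window `Date` (or ISO string) vector `c(start, end)`, end inclusive.
#' @param granularity `"quarter"` or `"year"`.
#' @return data.frame with columns `start` (inclusive) and `end` (exclusive),
#'   one row per interval in chronological order.
#' @export
build_timeline <- function(window, granularity = c("quarter", "year")) {
  granularity <- match.arg(granularity)
  window <- as_date_strict(window, "observation window")
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be c(start, end) with start <= end", call. = FALSE)
  step <- if (granularity == "quarter") 3L else 12L
  start_m <- as.integer(format(window[1], "%m"))
  if (as.integer(format(window[1], "%d")) != 1L || (start_m - 1L) %% step != 0L)
    stop(sprintf("window start %s is not aligned to a %s boundary",
                 window[1], granularity), call. = FALSE)
  end_excl <- window[2] + 1L
  end_m <- as.integer(format(end_excl, "%m"))
  if (as.integer(format(end_excl, "%d")) != 1L || (end_m - 1L) %% step != 0L)
    stop(sprintf("window end %s is not aligned to a %s boundary",
                 window[2], granularity), call. = FALSE)
  starts <- seq(window[1], end_excl, by = sprintf("%d months", step))
  data.frame(start = starts[-length(starts)], end = starts[-1])
}

# Map dates to timeline interval index; 0 / nrow+1 when outside the window.
interval_index <- function(dates, timeline) {
  findInterval(as.numeric(dates),
               as.numeric(c(timeline$start, timeline$end[nrow(timeline)])))
}

#' Encode per-patient events into state sequences for one dimension
#'
#' For every interval of the timeline the state is the combination of event
#' flags observed in that interval:
#' * `hcp_contact`: `O` iff at least one `OUTPATIENT_CONTACT` event in the
#'   outpatient setting falls in the quarter (hospital-outpatient contacts
#'   never satisfy the flag);
#' * `diagnostics`: `H` iff at least one outpatient `HBA1C` event; `B` iff
#'   the summed `STRIPS_RX` quantity in the quarter reaches
#'   `strips_threshold` (multiple prescriptions within a quarter are summed
#'   before thresholding);
#' * `screening`: letters `R`/`C`/`T` for the screening events observed in
#'   the year.
#'
#' Events dated outside the timeline are ignored with a warning. Encoding is
#' independent of event row order.
#'
#' @param events data.frame of event records (`patient_id`, `date`,
#'   `event_code`, `quantity`, `setting`) for any number of patients.
#' @param dimension dimension name, see [state_alphabet()].
#' @param timeline from [build_timeline()] with the dimension's granularity.
#' @param patient_ids patients to encode (rows of the result); defaults to
#'   the patients present in `events`.
#' @param strips_threshold minimum quarterly strips quantity for the `B`
#'   flag (default 200).
#' @return character matrix of states, one row per patient (rownames =
#'   patient ids), one column per interval.
#' @export
encode_dimension <- function(events, dimension, timeline,
                             patient_ids = NULL, strips_threshold = 200) {
  alph <- state_alphabet(dimension)
  if (is.null(patient_ids)) patient_ids <- sort(unique(events$patient_id))
  n <- length(patient_ids)
  ni <- nrow(timeline)
  dates <- as_date_strict(events$date, "event date")
  iv <- interval_index(dates, timeline)
  outside <- iv < 1L | iv > ni
  relevant <- events$event_code %in% alph$events & events$patient_id %in% patient_ids
  if (any(outside & relevant)) {
    warning(sprintf("%d event(s) dated outside the timeline were ignored",
                    sum(outside & relevant)), call. = FALSE)
  }
  keep <- relevant & !outside
  ev <- events[keep, , drop = FALSE]
  iv <- iv[keep]
  pid <- match(ev$patient_id, patient_ids)

  flag_matrix <- function(sel) {
    f <- matrix(FALSE, n, ni)
    if (any(sel)) f[cbind(pid[sel], iv[sel])] <- TRUE
    f
  }

  if (dimension == "hcp_contact") {
    has_o <- flag_matrix(ev$event_code == "OUTPATIENT_CONTACT" &
                           ev$setting == "outpatient")
    states <- ifelse(has_o, "O", "N")
  } else if (dimension == "diagnostics") {
    has_h <- flag_matrix(ev$event_code == "HBA1C" & ev$setting == "outpatient")
    qty <- matrix(0, n, ni)
    sel <- ev$event_code == "STRIPS_RX"
    if (any(sel)) {
      if (anyNA(ev$quantity[sel]))
        stop("STRIPS_RX rows must carry a quantity", call. = FALSE)
      agg <- rowsum(ev$quantity[sel],
                    group = (pid[sel] - 1L) * ni + iv[sel])
      cell <- as.integer(rownames(agg))
      qty[cbind((cell - 1L) %/% ni + 1L, (cell - 1L) %% ni + 1L)] <- agg[, 1]
    }
    has_b <- qty >= strips_threshold
    states <- matrix("N", n, ni)
    states[has_h & !has_b] <- "H"
    states[!has_h & has_b] <- "B"
    states[has_h & has_b] <- "HB"
  } else {
    has_r <- flag_matrix(ev$event_code == "RETINOPATHY_SCREEN")
    has_c <- flag_matrix(ev$event_code == "CHOLESTEROL_SCREEN")
    has_t <- flag_matrix(ev$event_code == "THYROID_SCREEN")
    lab <- matrix(paste0(ifelse(has_r, "R", ""), ifelse(has_c, "C", ""),
                         ifelse(has_t, "T", "")), n, ni)
    lab[lab == ""] <- "N"
    states <- lab
  }
  states <- matrix(states, n, ni, dimnames = list(patient_ids, NULL))
  stopifnot(all(states %in% alph$states))
  states
}

#' Encode all three dimensions for a cohort
#'
#' @param events event table.
#' @param patient_ids cohort patient ids (row order of the outputs).
#' @param window observation window `c(start, end)`.
#' @param strips_threshold quarterly strips threshold, see
#'   [encode_dimension()].
#' @return named list of three state matrices (`hcp_contact`, `diagnostics`:
#'   12 columns; `screening`: 3 columns).
#' @export
encode_cohort <- function(events, patient_ids,
                          window = c("2017-01-01", "2019-12-31"),
                          strips_threshold = 200) {
  qt <- build_timeline(window, "quarter")
  yt <- build_timeline(window, "year")
  list(
    hcp_contact = encode_dimension(events, "hcp_contact", qt, patient_ids,
                                   strips_threshold),
    diagnostics = encode_dimension(events, "diagnostics", qt, patient_ids,
                                   strips_threshold),
    screening = encode_dimension(events, "screening", yt, patient_ids,
                                 strips_threshold))
}

#' Assess guideline adherence of one patient's sequences
#'
#' The guideline reference for the 3-year window: an outpatient contact in
#' all 12 quarters; an HbA1c measurement and a >=200 test-strip supply in all
#' 12 quarters; at least 2 years with a retinopathy screen, at least 2 years
#' with a thyroid screen, and at least 1 year with a cholesterol screen.
#'
#' @param hcp,diagnostics,screening state vectors for one patient (length 12,
#'   12, 3).
#' @return list with per-requirement booleans, the underlying counts, and
#'   `perfect` (all requirements met).
#' @export
assess_adherence <- function(hcp, diagnostics, screening) {
  if (length(hcp) != 12L || length(diagnostics) != 12L || length(screening) != 3L)
    stop("adherence assessment needs all three dimensions (12/12/3 intervals)",
         call. = FALSE)
  counts <- list(
    contact_quarters = sum(hcp == "O"),
    hba1c_quarters = sum(diagnostics %in% c("H", "HB")),
    strips_quarters = sum(diagnostics %in% c("B", "HB")),
    retinopathy_years = sum(grepl("R", screening, fixed = TRUE)),
    cholesterol_years = sum(grepl("C", screening, fixed = TRUE)),
    thyroid_years = sum(grepl("T", screening, fixed = TRUE)))
  met <- list(
    quarterly_contact = counts$contact_quarters == 12L,
    quarterly_hba1c = counts$hba1c_quarters == 12L,
    quarterly_strips = counts$strips_quarters == 12L,
    retinopathy_2of3 = counts$retinopathy_years >= 2L,
    thyroid_2of3 = counts$thyroid_years >= 2L,
    cholesterol_1of3 = counts$cholesterol_years >= 1L)
  c(met, counts, list(perfect = all(unlist(met))))
}

#' Long-format export of a state matrix
#'
#' @param states state matrix from [encode_dimension()].
#' @return data.frame with `patient_id`, `interval_index`, `state`.
#' @export
sequences_long <- function(states) {
  data.frame(
    patient_id = rep(rownames(states), times = ncol(states)),
    interval_index = rep(seq_len(ncol(states)), each = nrow(states)),
    state = as.vector(states),
    stringsAsFactors = FALSE)
}
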
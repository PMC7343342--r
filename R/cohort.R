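#' Study windows for cohort construction
#'
#' Defaults mirror the study design: index events are sought in the
#' identification period 2009-07-01 to 2012-12-31, eligibility requires a
#' 6-calendar-month baseline and 365 days of follow-up, and observation is
#' censored at the study end 2013-12-31.
#'
#' @param id_period_start,id_period_end identification-period bounds.
#' @param baseline_months baseline length in calendar months (counted back
#'   from the index date with day-of-month clamping, not a fixed day count).
#' @param followup_days fixed follow-up length in days (index day included,
#'   so 365 gives `[index, index + 364]`).
#' @param study_end last day of the data window.
#' @return a `study_windows` list.
#' @export
study_windows <- function(id_period_start = "2009-07-01",
                          id_period_end = "2012-12-31",
                          baseline_months = 6L,
                          followup_days = 365L,
                          study_end = "2013-12-31") {
  w <- list(id_period_start = as.IDate(id_period_start),
            id_period_end = as.IDate(id_period_end),
            baseline_months = as.integer(baseline_months),
            followup_days = as.integer(followup_days),
            study_end = as.IDate(study_end))
  stopifnot(w$id_period_start <= w$id_period_end,
            w$id_period_end <= w$study_end,
            w$baseline_months > 0L, w$followup_days > 0L)
  class(w) <- "study_windows"
  w
}

## shift a date by n calendar months, clamping to the end of the target
## month (2009-03-31 minus 1 month -> 2009-02-28)
add_months <- function(dates, n) {
  if (!length(dates)) return(as.IDate(integer()))
  lt <- as.POSIXlt(as.Date(dates))
  lt$mon <- lt$mon + n
  day <- lt$mday
  lt$mday <- 1L
  first <- as.Date(lt)
  nxt <- as.POSIXlt(first)
  nxt$mon <- nxt$mon + 1L
  last_day <- as.integer(format(as.Date(nxt) - 1L, "%d"))
  as.IDate(first + pmin(day, last_day) - 1L)
}

#' Find a patient's index date
#'
#' The index date is the earliest `service_start` among the patient's
#' medical claims that carry an SCD diagnosis in any position and fall
#' inside the identification period.
#'
#' @param claims medical claims of a single patient.
#' @param windows a [study_windows()] object.
#' @param code_set SCD identification codes (undotted), default
#'   [scd_codes()].
#' @return an `IDate`, or `NA` when the patient has no qualifying claim.
#' @export
find_index_date <- function(claims, windows = study_windows(),
                            code_set = scd_codes()) {
  claims <- as.data.table(claims)
  if (!nrow(claims)) return(as.IDate(NA))
  if (uniqueN(claims$patient_id) > 1L) {
    stop("find_index_date() expects claims of a single patient")
  }
  hit <- claims[dx_has_any(dx_codes, code_set) &
                  service_start >= windows$id_period_start &
                  service_start <= windows$id_period_end]
  if (!nrow(hit)) return(as.IDate(NA))
  min(hit$service_start)
}

#' Test continuous enrollment around an index date
#'
#' TRUE iff every day in `[index - baseline_months, index + followup_days -
#' 1]` is covered by enrollment spans carrying both medical and pharmacy
#' coverage, allowing at most `allowable_gap` uncovered days in total
#' (default 0, i.e. strictly continuous).
#'
#' @param spans enrollment spans of one patient (normalized or not).
#' @param index_date the index date.
#' @param windows a [study_windows()] object.
#' @param allowable_gap maximum total uncovered days tolerated.
#' @return logical scalar.
#' @export
has_continuous_enrollment <- function(spans, index_date,
                                      windows = study_windows(),
                                      allowable_gap = 0L) {
  index_date <- as.IDate(index_date)
  win_start <- add_months(index_date, -windows$baseline_months)
  win_end <- index_date + windows$followup_days - 1L
  .uncovered_days(as.data.table(spans), win_start, win_end) <= allowable_gap
}

## total uncovered days in [win_start, win_end] given one patient's spans
## (both coverage flags required)
.uncovered_days <- function(spans, win_start, win_end) {
  spans <- spans[medical_coverage & pharmacy_coverage]
  if (!nrow(spans)) return(as.integer(win_end - win_start + 1L))
  spans <- normalize_enrollment(spans)
  s <- pmax(as.integer(spans$span_start), as.integer(win_start))
  e <- pmin(as.integer(spans$span_end), as.integer(win_end))
  covered <- sum(pmax(e - s + 1L, 0L))
  as.integer(win_end - win_start + 1L) - covered
}

#' Build the study cohort and the selection attrition table
#'
#' Applies the eligibility cascade in order: (1) an SCD-coded claim in the
#' identification period (index date), (2) age >= 18 at index, (3)
#' continuous medical + pharmacy enrollment over baseline and follow-up,
#' (4) no clinical-trial enrollment. Follow-up is censored at the earliest
#' of disenrollment, death, study end, and `index + followup_days - 1`;
#' death truncates follow-up but does not remove the patient.
#'
#' @param bundle a [claims_bundle()].
#' @param windows a [study_windows()] object.
#' @param allowable_gap see [has_continuous_enrollment()].
#' @param min_age minimum age at index (years), default 18.
#' @return a list with `cohort` (one row per eligible patient: index date,
#'   baseline/follow-up windows, actual follow-up end, age, plan type) and
#'   `attrition` (criterion label, patients remaining after each step).
#' @export
build_cohort <- function(bundle, windows = study_windows(),
                         allowable_gap = 0L, min_age = 18L) {
  pts <- bundle$patients
  med <- bundle$medical

  ## step 1: index date = first SCD claim in the ID period
  idx <- med[dx_has_any(dx_codes, scd_codes()) &
               service_start >= windows$id_period_start &
               service_start <= windows$id_period_end,
             .(index_date = min(service_start)), by = patient_id]
  cand <- pts[idx, on = "patient_id", nomatch = NULL]
  att <- data.table(criterion = "All patients in data", n_remaining = nrow(pts))
  att <- rbind(att, data.table(
    criterion = "SCD diagnosis in identification period",
    n_remaining = nrow(cand)))

  ## step 2: age at index
  cand[, age_at_index := .age_years(birth_date, index_date)]
  cand <- cand[age_at_index >= min_age]
  att <- rbind(att, data.table(
    criterion = sprintf("Age >=%d at index date", min_age),
    n_remaining = nrow(cand)))

  ## step 3: continuous enrollment over baseline + follow-up
  enr <- normalize_enrollment(bundle$enrollment[medical_coverage &
                                                  pharmacy_coverage])
  cand[, baseline_start := add_months(index_date, -windows$baseline_months)]
  cand[, baseline_end := index_date - 1L]
  cand[, followup_start := index_date]
  cand[, followup_end := index_date + windows$followup_days - 1L]
  if (nrow(cand)) {
    cov <- enr[cand[, .(patient_id, baseline_start, followup_end)],
               on = .(patient_id,
                      span_start <= followup_end, span_end >= baseline_start),
               .(covered = sum(pmax(
                 pmin(as.integer(x.span_end), as.integer(i.followup_end)) -
                   pmax(as.integer(x.span_start), as.integer(i.baseline_start)) +
                   1L, 0L))),
               by = .EACHI, nomatch = NA]
    cov <- cov[, .(covered = sum(covered, na.rm = TRUE)), by = patient_id]
    cand[cov, covered := i.covered, on = "patient_id"]
    cand[is.na(covered), covered := 0L]
    cand <- cand[as.integer(followup_end - baseline_start + 1L) - covered <=
                   allowable_gap]
  }
  att <- rbind(att, data.table(
    criterion = "Continuous enrollment (baseline + follow-up)",
    n_remaining = nrow(cand)))

  ## step 4: clinical-trial exclusion
  cand <- cand[clinical_trial_flag == FALSE]
  att <- rbind(att, data.table(
    criterion = "Not enrolled in a clinical trial",
    n_remaining = nrow(cand)))

  ## actual follow-up end: min(disenrollment, death, study end, fixed end)
  if (nrow(cand)) {
    cov_end <- enr[cand[, .(patient_id, followup_start)],
                   on = .(patient_id, span_start <= followup_start,
                          span_end >= followup_start),
                   .(cov_end = max(x.span_end)), by = .EACHI, nomatch = NA]
    cand[cov_end, followup_end_actual := as.IDate(pmin(
      as.integer(followup_end),
      fifelse(is.na(i.cov_end), .Machine$integer.max, as.integer(i.cov_end)),
      as.integer(windows$study_end),
      fifelse(is.na(death_date), .Machine$integer.max, as.integer(death_date))
    )), on = "patient_id"]
  } else {
    cand[, followup_end_actual := as.IDate(integer())]
  }

  cohort <- cand[, .(patient_id, index_date, baseline_start, baseline_end,
                     followup_start, followup_end, followup_end_actual,
                     age_at_index, plan_type)]
  setorder(cohort, patient_id)
  list(cohort = cohort[], attrition = att[])
}

## completed years between two dates (birthday arithmetic, not /365.25)
.age_years <- function(birth, at) {
  b <- as.POSIXlt(as.Date(birth)); a <- as.POSIXlt(as.Date(at))
  age <- a$year - b$year
  before_bday <- a$mon < b$mon | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - before_bday)
}
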
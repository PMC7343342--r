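#' Hand-designed eligibility stress fixture
#'
#' A fixed 12-patient bundle in which each eligibility rule fails for
#' exactly one designed patient: P04 has an SCD claim only before the
#' identification period, P12 has no claims, P05 is under 18 at index, P06
#' has a 29-day baseline enrollment gap, P07 loses coverage during
#' follow-up, P08 lacks pharmacy coverage in baseline, and P09 carries the
#' clinical-trial flag. The five eligible patients (P01, P02, P03, P10,
#' P11) cover the episode strata 0/1/2/3+, both plan types, baseline VOC
#' burden (P11 has a pre-identification-period inpatient VOC episode in
#' baseline), Charlson scoring with the supersedes hierarchy, medication
#' and transfusion flags, and per-episode costing.
#'
#' Hand-computed expectations are attached as `attr(, "expected")`: the
#' attrition counts, the eligible id set, per-patient annual all-cause and
#' SCD-related cost totals (at unit CPI), episode windows/settings, and
#' baseline-profile values.
#'
#' @return a [claims_bundle()] with an `expected` attribute.
#' @export
generate_eligibility_fixture <- function() {
  d <- function(x) as.IDate(x)
  patients <- data.table(
    patient_id = sprintf("P%02d", 1:12),
    birth_date = d(c("1980-02-20", "1975-01-01", "1985-07-07", "1970-01-01",
                     "1993-06-01", "1982-03-03", "1979-11-11", "1984-04-04",
                     "1987-09-09", "1960-12-12", "1980-05-05", "1990-10-10")),
    sex = c("female", "male", "female", "male", "female", "male", "female",
            "male", "female", "male", "female", "male"),
    race = c("black", "black", "hispanic", "black", "black", "white",
             "black", "unknown", "black", "black", "black", "other"),
    region = c("northeast", "south", "northeast", "west", "south",
               "north_central", "northeast", "south", "west", "northeast",
               "south", "northeast"),
    plan_type = c("FFS", "managed_care", "FFS", "FFS", "FFS", "FFS", "FFS",
                  "FFS", "FFS", "FFS", "FFS", "FFS"),
    death_date = d(c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                     "2011-05-01", NA)),
    clinical_trial_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                            FALSE, TRUE, FALSE, FALSE, FALSE)
  )

  med <- function(id, pid, start, end, dx, pos, paid, transf = FALSE) {
    data.table(claim_id = id, patient_id = pid, service_start = d(start),
               service_end = d(end), dx_codes = dx, pos_code = pos,
               is_transfusion = transf, paid_amount = paid,
               service_year = as.integer(substr(start, 1, 4)))
  }
  medical <- rbind(
    ## P01: eligible FFS; asthma baseline, 2 follow-up episodes
    med("C101", "P01", "2010-01-15", "2010-01-15", "49390",
        "outpatient_office", 100),
    med("C102", "P01", "2010-03-10", "2010-03-10", "28260",
        "outpatient_hospital", 200),
    med("C103", "P01", "2010-04-01", "2010-04-05", "28262", "inpatient",
        10000),
    med("C104", "P01", "2010-04-03", "2010-04-03", "28262", "outpatient_er",
        800),
    med("C105", "P01", "2010-06-01", "2010-06-01", "28269", "outpatient_er",
        700),
    med("C106", "P01", "2010-08-01", "2010-08-01", "4019",
        "outpatient_office", 150),
    ## P02: eligible managed care; 1 ER episode
    med("C201", "P02", "2011-01-20", "2011-01-20", "28241",
        "outpatient_office", 220),
    med("C202", "P02", "2011-03-15", "2011-03-15", "28262", "outpatient_er",
        500),
    ## P03: eligible FFS; 4 office episodes
    med("C301", "P03", "2010-04-15", "2010-04-15", "28260",
        "outpatient_office", 250),
    med("C302", "P03", "2010-05-01", "2010-05-01", "28262",
        "outpatient_office", 300),
    med("C303", "P03", "2010-06-01", "2010-06-01", "28264",
        "outpatient_office", 300),
    med("C304", "P03", "2010-07-01", "2010-07-01", "28262",
        "outpatient_office", 300),
    med("C305", "P03", "2010-08-01", "2010-08-01", "28269",
        "outpatient_office", 300),
    ## P04: SCD claim only before the identification period
    med("C401", "P04", "2009-06-15", "2009-06-15", "28260",
        "outpatient_hospital", 100),
    med("C402", "P04", "2010-01-10", "2010-01-10", "4019",
        "outpatient_office", 50),
    ## P05: under 18 at index
    med("C501", "P05", "2010-05-01", "2010-05-01", "28260",
        "outpatient_hospital", 100),
    ## P06: baseline enrollment gap
    med("C601", "P06", "2010-09-15", "2010-09-15", "28260",
        "outpatient_hospital", 100),
    ## P07: follow-up enrollment gap
    med("C701", "P07", "2010-02-10", "2010-02-10", "28261",
        "outpatient_hospital", 100),
    ## P08: no pharmacy coverage in baseline
    med("C801", "P08", "2011-05-05", "2011-05-05", "28260",
        "outpatient_hospital", 100),
    ## P09: clinical-trial exclusion
    med("C901", "P09", "2010-10-01", "2010-10-01", "28260",
        "outpatient_hospital", 100),
    ## P10: eligible FFS, zero baseline claims, zero episodes
    med("C1001", "P10", "2012-06-30", "2012-06-30", "28263",
        "outpatient_hospital", 120),
    ## P11: eligible FFS; baseline CCI/meds/transfusion and a baseline
    ## inpatient VOC episode dated before the identification period
    med("C1101", "P11", "2009-04-15", "2009-04-15", "25040;49390",
        "outpatient_office", 90),
    med("C1102", "P11", "2009-05-10", "2009-05-13", "28262", "inpatient",
        8000),
    med("C1103", "P11", "2009-06-20", "2009-06-20", "1628",
        "outpatient_hospital", 400, transf = TRUE),
    med("C1104", "P11", "2009-09-20", "2009-09-20", "28263",
        "outpatient_hospital", 180),
    med("C1105", "P11", "2010-01-05", "2010-01-05", "28262", "outpatient_er",
        900)
  )

  pharmacy <- data.table(
    claim_id = c("R101", "R102", "R103", "R104", "R105", "R106"),
    patient_id = c("P01", "P01", "P11", "P11", "P03", "P02"),
    fill_date = d(c("2010-02-01", "2010-04-02", "2009-08-01", "2009-12-01",
                    "2010-09-01", "2011-02-01")),
    drug_class = c("hydroxyurea", "opioid", "nsaid", "folic_acid", "other",
                   "opioid"),
    paid_amount = c(50, 30, 25, 20, 40, 35),
    service_year = c(2010L, 2010L, 2009L, 2009L, 2010L, 2011L)
  )

  span <- function(pid, s, e, m = TRUE, p = TRUE) {
    data.table(patient_id = pid, span_start = d(s), span_end = d(e),
               medical_coverage = m, pharmacy_coverage = p)
  }
  enrollment <- rbind(
    span("P01", "2009-08-01", "2011-12-31"),
    span("P02", "2010-06-01", "2012-03-01"),
    span("P03", "2009-09-01", "2011-06-30"),
    span("P04", "2009-01-01", "2011-12-31"),
    span("P05", "2009-10-01", "2011-06-01"),
    span("P06", "2010-03-01", "2010-07-17"),
    span("P06", "2010-08-16", "2011-12-31"),
    span("P07", "2009-08-01", "2010-08-29"),
    span("P08", "2010-11-05", "2011-05-04", m = TRUE, p = FALSE),
    span("P08", "2011-05-05", "2012-05-04"),
    span("P09", "2010-02-01", "2011-10-31"),
    span("P10", "2011-12-01", "2013-07-15"),
    span("P11", "2009-03-01", "2010-12-31"),
    span("P12", "2009-01-01", "2013-12-31")
  )

  bundle <- claims_bundle(patients, medical, pharmacy, enrollment)
  expected <- list(
    attrition = data.table(
      criterion = c("All patients in data",
                    "SCD diagnosis in identification period",
                    "Age >=18 at index date",
                    "Continuous enrollment (baseline + follow-up)",
                    "Not enrolled in a clinical trial"),
      n_remaining = c(12L, 10L, 9L, 6L, 5L)),
    eligible = c("P01", "P02", "P03", "P10", "P11"),
    index_dates = c(P01 = "2010-03-10", P02 = "2011-01-20",
                    P03 = "2010-04-15", P10 = "2012-06-30",
                    P11 = "2009-09-20"),
    ## per-patient annual totals at unit CPI, FFS members only
    all_cause_totals = c(P01 = 11880, P03 = 1490, P10 = 120, P11 = 1100),
    scd_totals = c(P01 = 11730, P03 = 1450, P10 = 120, P11 = 1100),
    episode_counts = c(P01 = 2L, P02 = 1L, P03 = 4L, P10 = 0L, P11 = 1L),
    episode_cost_by_setting = list(
      inpatient = c(n = 1, mean = 10830),
      er = c(n = 2, mean = 800),
      office = c(n = 4, mean = 300)),
    cci = c(P01 = 1L, P02 = 0L, P03 = 0L, P10 = 0L, P11 = 5L),
    cci_bands = c(P01 = "1", P02 = "0", P03 = "0", P10 = "0", P11 = "4+"),
    baseline_voc = c(P01 = 0L, P02 = 0L, P03 = 0L, P10 = 0L, P11 = 1L)
  )
  setattr(bundle, "expected", expected)
  bundle
}
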
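claims_row <- function(id, date, dx, pid = "P1") {
  data.table(claim_id = id, patient_id = pid,
             service_start = as.IDate(date), service_end = as.IDate(date),
             dx_codes = dx, pos_code = "outpatient_hospital",
             is_transfusion = FALSE, paid_amount = 1, service_year =
               as.integer(substr(date, 1, 4)))
}

test_that("index date is the earliest SCD claim inside the identification period", {
  w <- study_windows()
  expect_true(is.na(find_index_date(claims_row("A", "2010-01-01", "4019"), w)))
  ## SCD claim before the period start does not index
  expect_true(is.na(find_index_date(claims_row("A", "2009-06-15", "28262"), w)))
  cl <- rbind(claims_row("A", "2010-03-01", "28260"),
              claims_row("B", "2009-09-09", "28262"))
  expect_equal(find_index_date(cl, w), as.IDate("2009-09-09"))
  ## any diagnosis position counts
  expect_equal(find_index_date(claims_row("A", "2011-05-05", "4019;28261"), w),
               as.IDate("2011-05-05"))
})

test_that("continuous enrollment requires both coverages with zero gap by default", {
  w <- study_windows()
  idx <- as.IDate("2010-06-15")
  full <- data.table(patient_id = "P1", span_start = as.IDate("2009-11-01"),
                     span_end = as.IDate("2011-07-01"),
                     medical_coverage = TRUE, pharmacy_coverage = TRUE)
  expect_true(has_continuous_enrollment(full, idx, w))
  ## one uncovered day at index - 30
  gap_day <- idx - 30L
  gapped <- rbind(
    data.table(patient_id = "P1", span_start = as.IDate("2009-11-01"),
               span_end = gap_day - 1L, medical_coverage = TRUE,
               pharmacy_coverage = TRUE),
    data.table(patient_id = "P1", span_start = gap_day + 1L,
               span_end = as.IDate("2011-07-01"), medical_coverage = TRUE,
               pharmacy_coverage = TRUE))
  expect_false(has_continuous_enrollment(gapped, idx, w))
  expect_true(has_continuous_enrollment(gapped, idx, w, allowable_gap = 1L))
  ## medical-only coverage in baseline fails
  med_only <- copy(full)
  med_only_base <- rbind(
    data.table(patient_id = "P1", span_start = as.IDate("2009-11-01"),
               span_end = idx - 1L, medical_coverage = TRUE,
               pharmacy_coverage = FALSE),
    data.table(patient_id = "P1", span_start = idx,
               span_end = as.IDate("2011-07-01"), medical_coverage = TRUE,
               pharmacy_coverage = TRUE))
  expect_false(has_continuous_enrollment(med_only_base, idx, w))
})

test_that("the 6-month baseline is calendar months with day clamping", {
  ch <- build_cohort(generate_eligibility_fixture())$cohort
  expect_equal(ch[patient_id == "P01", baseline_start],
               as.IDate("2009-09-10"))  # 2010-03-10 minus 6 months
})

test_that("the eligibility stress fixture reproduces its hand-computed attrition", {
  fx <- generate_eligibility_fixture()
  exp <- attr(fx, "expected")
  ch <- build_cohort(fx)
  expect_equal(as.data.frame(ch$attrition), as.data.frame(exp$attrition))
  expect_setequal(ch$cohort$patient_id, exp$eligible)
  expect_equal(as.character(ch$cohort$index_date),
               unname(exp$index_dates[ch$cohort$patient_id]))
  ## attrition counts never increase down the cascade
  expect_true(all(diff(ch$attrition$n_remaining) <= 0))
})

test_that("single-rule toggles flip exactly the designed patient", {
  fx <- generate_eligibility_fixture()
  base_n <- nrow(build_cohort(fx)$cohort)
  ## clearing the clinical-trial flag admits P09
  fx2 <- generate_eligibility_fixture()
  fx2$patients[patient_id == "P09", clinical_trial_flag := FALSE]
  ch2 <- build_cohort(fx2)
  expect_equal(nrow(ch2$cohort), base_n + 1L)
  expect_true("P09" %in% ch2$cohort$patient_id)
  ## closing P06's 29-day baseline gap admits P06
  fx3 <- generate_eligibility_fixture()
  fx3$enrollment[patient_id == "P06" & span_start == as.IDate("2010-08-16"),
                 span_start := as.IDate("2010-07-18")]
  ch3 <- build_cohort(fx3)
  expect_true("P06" %in% ch3$cohort$patient_id)
})

test_that("cohort construction is order-invariant and per-patient", {
  fx <- generate_eligibility_fixture()
  ref <- build_cohort(fx)
  set.seed(99)
  shuf <- claims_bundle(fx$patients[sample(.N)], fx$medical[sample(.N)],
                        fx$pharmacy[sample(.N)], fx$enrollment[sample(.N)])
  got <- build_cohort(shuf)
  expect_equal(as.data.frame(got$cohort), as.data.frame(ref$cohort))
  expect_equal(as.data.frame(got$attrition), as.data.frame(ref$attrition))
  ## dropping an unrelated patient leaves others' eligibility unchanged
  keep <- fx$patients$patient_id != "P03"
  sub <- claims_bundle(fx$patients[keep],
                       fx$medical[patient_id != "P03"],
                       fx$pharmacy[patient_id != "P03"],
                       fx$enrollment[patient_id != "P03"])
  expect_setequal(build_cohort(sub)$cohort$patient_id,
                  setdiff(ref$cohort$patient_id, "P03"))
})

test_that("an all-minor population zeroes out at the age step", {
  fx <- generate_eligibility_fixture()
  fx$patients[, birth_date := as.IDate("2005-01-01")]
  ch <- build_cohort(fx)
  expect_equal(nrow(ch$cohort), 0L)
  expect_equal(ch$attrition[criterion == "Age >=18 at index date",
                            n_remaining], 0L)
})

test_that("death truncates follow-up but keeps the patient", {
  fx <- generate_eligibility_fixture()
  fx$patients[patient_id == "P01", death_date := as.IDate("2010-09-01")]
  ch <- build_cohort(fx)
  expect_true("P01" %in% ch$cohort$patient_id)
  expect_equal(ch$cohort[patient_id == "P01", followup_end_actual],
               as.IDate("2010-09-01"))
})
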
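test_that("ICD-9 code normalization strips and restores dots", {
  expect_equal(icd9_strip("282.62"), "28262")
  expect_equal(icd9_strip(c(" 282.41", "v43.4")), c("28241", "V434"))
  expect_equal(icd9_dotted("28262"), "282.62")
  expect_equal(icd9_dotted("E8121"), "E812.1")
  expect_equal(icd9_dotted("496"), "496")
  expect_true(all(voc_codes() %in% scd_codes()))
})

test_that("bundle write/read round trip reproduces records exactly", {
  fx <- generate_eligibility_fixture()
  dir <- withr::local_tempdir()
  write_claims_bundle(fx, dir)
  back <- read_claims_bundle(dir)
  expect_equal(nrow(attr(back, "rejected")), 0L)
  for (tab in c("patients", "medical", "pharmacy", "enrollment")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(fx[[tab]]),
                 info = tab)
  }
})

test_that("empty claims file with a valid header loads as empty", {
  fx <- generate_eligibility_fixture()
  dir <- withr::local_tempdir()
  write_claims_bundle(fx, dir)
  fwrite(fx$medical[0], file.path(dir, "medical.csv"))
  b <- read_claims_bundle(dir)
  expect_equal(nrow(b$medical), 0L)
  expect_equal(nrow(attr(b, "rejected")), 0L)
})

test_that("missing required column is a hard error naming the column", {
  fx <- generate_eligibility_fixture()
  dir <- withr::local_tempdir()
  write_claims_bundle(fx, dir)
  fwrite(fx$medical[, !"pos_code"], file.path(dir, "medical.csv"))
  expect_error(read_claims_bundle(dir), "pos_code")
})

test_that("invalid rows abort in strict mode and are dropped with diagnostics in skip mode", {
  fx <- generate_eligibility_fixture()
  bad_med <- copy(fx$medical)
  bad_med[1, `:=`(service_start = as.IDate("2010-05-01"),
                  service_end = as.IDate("2010-04-01"))]
  bad_med[2, paid_amount := -5]
  dir <- withr::local_tempdir()
  write_claims_bundle(fx, dir)
  fwrite(bad_med, file.path(dir, "medical.csv"))
  expect_error(read_claims_bundle(dir), "service_end before service_start")
  b <- read_claims_bundle(dir, on_error = "skip")
  rej <- attr(b, "rejected")
  expect_setequal(rej$message, c("service_end before service_start",
                                 "missing or negative paid_amount"))
  expect_equal(nrow(b$medical), nrow(fx$medical) - 2L)
})

test_that("multi-diagnosis strings keep position order and dotted input is normalized", {
  med <- data.table(claim_id = c("A", "B"), patient_id = "P1",
                    service_start = as.IDate("2013-02-01"),
                    service_end = as.IDate("2013-02-01"),
                    dx_codes = c("401.9;282.62", "486"),
                    pos_code = "outpatient_hospital", is_transfusion = FALSE,
                    paid_amount = 10, service_year = 2013L)
  b <- one_patient_bundle(med)
  expect_equal(b$medical$dx_codes, c("4019;28262", "486"))
  voc <- identify_voc_claims(b$medical)
  expect_equal(voc$claim_id, "A")  # VOC code found in second position
})

test_that("normalize_enrollment merges abutting spans and handles empty input", {
  empty <- data.table(patient_id = character(),
                      span_start = as.IDate(integer()),
                      span_end = as.IDate(integer()),
                      medical_coverage = logical(),
                      pharmacy_coverage = logical())
  expect_equal(nrow(normalize_enrollment(empty)), 0L)
  spans <- data.table(patient_id = "P1",
                      span_start = as.IDate(c("2010-01-01", "2010-04-01")),
                      span_end = as.IDate(c("2010-03-31", "2010-06-30")),
                      medical_coverage = TRUE, pharmacy_coverage = TRUE)
  merged <- normalize_enrollment(spans)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$span_start, as.IDate("2010-01-01"))
  expect_equal(merged$span_end, as.IDate("2010-06-30"))
})

test_that("normalize_enrollment preserves the covered-day set and is idempotent", {
  set.seed(404)
  base <- as.IDate("2010-01-01")
  for (rep in 1:10) {
    n <- 50L
    starts <- base + sample(0:330, n, replace = TRUE)
    spans <- data.table(
      patient_id = sample(c("A", "B", "C"), n, replace = TRUE),
      span_start = starts,
      span_end = starts + sample(0:40, n, replace = TRUE),
      medical_coverage = sample(c(TRUE, FALSE), n, replace = TRUE),
      pharmacy_coverage = TRUE)
    norm <- normalize_enrollment(spans)
    ## brute-force day-set oracle per patient and flag combination
    key <- function(dt) dt[, paste(patient_id, medical_coverage,
                                   pharmacy_coverage)]
    for (k in unique(key(spans))) {
      days_raw <- spans[key(spans) == k,
                        unlist(Map(seq, as.integer(span_start),
                                   as.integer(span_end)))]
      days_norm <- norm[key(norm) == k,
                        unlist(Map(seq, as.integer(span_start),
                                   as.integer(span_end)))]
      expect_equal(sort(unique(days_raw)), sort(days_norm))
      expect_false(anyDuplicated(days_norm) > 0)  # disjoint after merge
    }
    expect_equal(as.data.frame(normalize_enrollment(norm)),
                 as.data.frame(norm))
  }
})

test_that("constructor rejects invariant violations", {
  fx <- generate_eligibility_fixture()
  bad <- copy(fx$patients)
  bad[2, patient_id := bad$patient_id[1]]
  expect_error(claims_bundle(bad, fx$medical, fx$pharmacy, fx$enrollment),
               "duplicate patient_id")
})
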
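day_claim <- function(id, day, pos = "outpatient_er", end_day = day,
                      pid = "PX", dx = "28262") {
  base <- as.IDate("2010-06-01")
  data.table(claim_id = id, patient_id = pid,
             service_start = base + day, service_end = base + end_day,
             dx_codes = dx, pos_code = pos, is_transfusion = FALSE,
             paid_amount = 1, service_year = 2010L)
}

test_that("VOC claim identification uses the VOC subset in any position", {
  expect_equal(nrow(identify_voc_claims(day_claim("A", 0, dx = "28260"))), 0L)
  expect_equal(nrow(identify_voc_claims(
    day_claim("A", 0, dx = "4019;486;28262"))), 1L)
  empty <- day_claim("A", 0)[0]
  expect_equal(nrow(identify_voc_claims(empty)), 0L)
})

test_that("the 3-day gap rule merges day 1 + day 4 but not day 1 + day 5", {
  cl <- rbind(day_claim("A", 1), day_claim("B", 4))
  eps <- merge_into_episodes(cl, gap_days = 3L)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$duration_days, 4L)
  cl2 <- rbind(day_claim("A", 1), day_claim("B", 5))
  expect_equal(nrow(merge_into_episodes(cl2, gap_days = 3L)), 2L)
})

test_that("overlapping claims merge and episode end extends to the max service end", {
  cl <- rbind(day_claim("A", 1, pos = "inpatient", end_day = 10),
              day_claim("B", 2))
  eps <- merge_into_episodes(cl)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$duration_days, 10L)
  expect_equal(eps$setting, "inpatient")
  expect_equal(eps$n_claims, 2L)
})

test_that("mixed patient ids are rejected", {
  cl <- rbind(day_claim("A", 1, pid = "P1"), day_claim("B", 2, pid = "P2"))
  expect_error(merge_into_episodes(cl), "single patient")
})

test_that("sequential merge equals the connected-components oracle on random sets", {
  set.seed(2024)
  for (rep in 1:150) {
    n <- sample(1:40, 1)
    cl <- random_claim_set(n)
    gap <- sample(0:6, 1)
    eps <- merge_into_episodes(cl, gap_days = gap)
    orc <- oracle_episodes(as.integer(cl$service_start),
                           as.integer(cl$service_end), gap)
    expect_equal(as.integer(eps$start), orc$start)
    expect_equal(as.integer(eps$end), orc$end)
    expect_equal(eps$n_claims, orc$n_claims)
  }
})

test_that("episode count is non-increasing in the gap and partitions the claims", {
  set.seed(515)
  for (rep in 1:40) {
    cl <- random_claim_set(sample(2:30, 1))
    counts <- vapply(0:10, function(g) {
      nrow(merge_into_episodes(cl, gap_days = g))
    }, 0L)
    expect_true(all(diff(counts) <= 0))
    ## a gap at least the whole observed span merges everything
    span <- as.integer(max(cl$service_end) - min(cl$service_start))
    expect_equal(nrow(merge_into_episodes(cl, gap_days = span)), 1L)
    ## partition: every claim in exactly one episode; inter-episode
    ## separation exceeds the gap
    eps <- merge_into_episodes(cl, gap_days = 3L)
    members <- unlist(strsplit(eps$member_claim_ids, ";"))
    expect_setequal(members, cl$claim_id)
    expect_equal(length(members), nrow(cl))
    if (nrow(eps) > 1L) {
      expect_true(all(as.integer(eps$start[-1]) -
                        as.integer(eps$end[-nrow(eps)]) > 3L))
    }
  }
})

test_that("setting classification follows the inpatient > ER > outpatient > office > other hierarchy", {
  expect_equal(classify_setting(c("outpatient_er", "inpatient")), "inpatient")
  expect_equal(classify_setting("outpatient_office"), "office")
  expect_equal(classify_setting(c("long_term_care", "outpatient_office")),
               "outpatient")
  expect_equal(classify_setting(c("lab", "hospice")), "other")
  expect_error(classify_setting("spaceship"), "spaceship")
  ## every facility type maps to exactly one setting
  expect_setequal(names(setting_hierarchy()$pos_to_setting), facility_types())
})

test_that("episode counting is restricted to the follow-up window by start date", {
  cohort <- data.table(patient_id = "PX",
                       followup_start = as.IDate("2010-06-01"),
                       followup_end = as.IDate("2011-05-31"))
  eps0 <- merge_into_episodes(day_claim("A", 0)[0])
  expect_equal(count_and_stratify(eps0, cohort)$n_episodes, 0L)
  expect_equal(as.character(count_and_stratify(eps0, cohort)$stratum), "0")
  cl <- rbind(day_claim("A", 0), day_claim("B", 10), day_claim("C", 20),
              day_claim("D", 30), day_claim("E", 40))
  eps5 <- merge_into_episodes(cl)
  cs <- count_and_stratify(eps5, cohort)
  expect_equal(cs$n_episodes, 5L)
  expect_equal(as.character(cs$stratum), "3+")
  ## an episode starting after the window end is not counted
  late <- merge_into_episodes(day_claim("Z", 400))
  expect_equal(count_and_stratify(late, cohort)$n_episodes, 0L)
})
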
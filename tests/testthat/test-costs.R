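test_that("CPI adjustment is the identity at the reference year and linear", {
  cpi <- c(`2012` = 1.1, `2013` = 1.0)
  expect_equal(adjust_cost(100, 2013, cpi), 100)
  expect_equal(adjust_cost(100, 2012, cpi), 110)
  x <- c(10, 25, 7.5)
  expect_equal(sum(adjust_cost(x, 2012, cpi)), adjust_cost(sum(x), 2012, cpi))
  expect_error(adjust_cost(100, 2008, cpi), "2008")
  expect_error(load_cpi_table(withr::local_tempfile(
    lines = c("reference_year: 2013", "factors:", "  2013: 1.1"))),
    "reference-year")
})

test_that("SCD-relatedness covers diagnoses in any position, transfusions, and drug classes", {
  med <- data.table(dx_codes = c("4019;28269", "4019", "4019"),
                    is_transfusion = c(FALSE, TRUE, FALSE))
  expect_equal(is_scd_related(med), c(TRUE, TRUE, FALSE))
  rx <- data.table(drug_class = c("hydroxyurea", "opioid", "other"))
  expect_equal(is_scd_related(rx), c(TRUE, TRUE, FALSE))
})

test_that("single-patient annual summary identities hold", {
  med <- data.table(claim_id = "A", patient_id = "P1",
                    service_start = as.IDate("2012-02-01"),
                    service_end = as.IDate("2012-02-03"),
                    dx_codes = "28262", pos_code = "inpatient",
                    is_transfusion = FALSE, paid_amount = 100,
                    service_year = 2012L)
  b <- one_patient_bundle(med)
  ch <- build_cohort(b)
  expect_equal(nrow(ch$cohort), 1L)
  for (scope in c("all_cause", "scd_related")) {
    s <- annual_summary(ch$cohort, b, scope, cpi = unit_cpi)
    ip <- s[facility == "inpatient"]
    expect_equal(ip$pct_with_visit, 100)
    expect_equal(ip$mean_cost, 100)
    expect_equal(ip$median_cost, 100)
    expect_equal(ip$mean_los, 3)
    expect_equal(s[facility == "total", mean_cost], 100)
  }
  ## the same claim without an SCD code contributes to all-cause only
  med2 <- rbind(copy(med)[, dx_codes := "4019"],
                copy(med)[, `:=`(claim_id = "IDX", dx_codes = "28260",
                                 pos_code = "outpatient_hospital",
                                 paid_amount = 0)])
  b2 <- one_patient_bundle(med2)
  ch2 <- build_cohort(b2)
  s_all <- annual_summary(ch2$cohort, b2, "all_cause", cpi = unit_cpi)
  s_scd <- annual_summary(ch2$cohort, b2, "scd_related", cpi = unit_cpi)
  expect_equal(s_all[facility == "inpatient", mean_cost], 100)
  expect_equal(s_scd[facility == "inpatient", mean_cost], 0)
})

test_that("fixture annual summaries equal the hand-summed per-patient ledgers", {
  fx <- generate_eligibility_fixture()
  exp <- attr(fx, "expected")
  ch <- build_cohort(fx)
  t3a <- annual_summary(ch$cohort, fx, "all_cause", cpi = unit_cpi)
  t3s <- annual_summary(ch$cohort, fx, "scd_related", cpi = unit_cpi)
  expect_equal(t3a[facility == "total", mean_cost],
               mean(exp$all_cause_totals))
  expect_equal(t3a[facility == "total", median_cost],
               median(exp$all_cause_totals))
  expect_equal(t3s[facility == "total", mean_cost], mean(exp$scd_totals))
  expect_equal(t3s[facility == "total", median_cost],
               median(exp$scd_totals))
  ## utilization percentages count managed-care members too
  expect_equal(t3a[facility == "inpatient", pct_with_visit], 20)
  expect_equal(t3a[facility == "outpatient_er", pct_with_visit], 60)
  expect_equal(t3a[facility == "pharmacy", pct_with_visit], 80)
  ## per-patient SCD-related totals match the ledger exactly
  tot <- patient_cost_totals(ch$cohort, fx, "scd_related", cpi = unit_cpi)
  setkey(tot, patient_id)
  expect_equal(tot[names(exp$scd_totals), total_cost], unname(exp$scd_totals))
})

test_that("per-episode costs include all in-window medical claims but only SCD-class fills", {
  fx <- generate_eligibility_fixture()
  exp <- attr(fx, "expected")
  ch <- build_cohort(fx)
  eps <- build_episodes(fx, ch$cohort)
  ec <- episode_costs(eps, fx, ch$cohort, cpi = unit_cpi)
  for (s in names(exp$episode_cost_by_setting)) {
    row <- ec$by_setting[setting == s]
    expect_equal(row$n_episodes, unname(exp$episode_cost_by_setting[[s]]["n"]))
    expect_equal(row$mean_cost, unname(exp$episode_cost_by_setting[[s]]["mean"]))
  }
  ## P01 episode 1: inpatient 10000 + same-window ER 800 + opioid fill 30
  e1 <- ec$episode_costs[episode_id == "P01-E1"]
  expect_equal(e1$medical_cost, 10800)
  expect_equal(e1$scd_pharmacy_cost, 30)
  expect_equal(e1$total_cost, 10830)
  ## managed-care member episodes are excluded from costing
  expect_false("P02" %in% ec$episode_costs$patient_id)
  ## a non-SCD medical claim inside the window is included; a non-SCD-class
  ## fill is excluded
  med <- rbind(
    data.table(claim_id = c("IDX", "V1", "BG"), patient_id = "P1",
               service_start = as.IDate(c("2012-01-10", "2012-03-01",
                                          "2012-03-02")),
               service_end = as.IDate(c("2012-01-10", "2012-03-03",
                                        "2012-03-02")),
               dx_codes = c("28260", "28262", "4019"),
               pos_code = c("outpatient_hospital", "inpatient",
                            "outpatient_other"),
               is_transfusion = FALSE, paid_amount = c(0, 50, 17),
               service_year = 2012L))
  rx <- data.table(claim_id = c("F1", "F2"), patient_id = "P1",
                   fill_date = as.IDate("2012-03-02"),
                   drug_class = c("opioid", "other"),
                   paid_amount = c(5, 99), service_year = 2012L)
  b <- one_patient_bundle(med, rx)
  chx <- build_cohort(b)
  epx <- build_episodes(b, chx$cohort)
  ecx <- episode_costs(epx, b, chx$cohort, cpi = unit_cpi)
  expect_equal(ecx$episode_costs$medical_cost, 67)       # 50 + 17
  expect_equal(ecx$episode_costs$scd_pharmacy_cost, 5)   # opioid only
  expect_equal(ecx$episode_costs$total_cost, 72)
})

test_that("stratified summaries partition the cohort and use SCD-related claims", {
  fx <- generate_eligibility_fixture()
  ch <- build_cohort(fx)
  eps <- build_episodes(fx, ch$cohort)
  ss <- stratified_summary(ch$cohort, fx, eps, cpi = unit_cpi)
  expect_equal(sum(ss$strata$n_patients), nrow(ch$cohort))
  expect_equal(ss$strata$n_patients, c(1L, 2L, 1L, 1L))  # strata 0/1/2/3+
  ## the single zero-episode patient is P10 with SCD total 120
  expect_equal(ss$costs[stratum == "0" & facility == "total", mean_cost], 120)
})

test_that("cost frequency distribution drops zero totals and matches a histogram oracle", {
  totals <- data.table(patient_id = sprintf("P%d", 1:5),
                       total_cost = c(0, 10, 20, 30, 0),
                       stratum = episode_stratum(c(0L, 1L, 1L, 5L, 2L)))
  d <- cost_frequency_distribution(totals, breaks = c(0, 15, 40))
  expect_equal(sum(d$bins$n), 3L)
  expect_equal(d$summary[stratum == "3+", max_total], 30)
  expect_equal(d$summary[, sum(n)], 3L)
  ## oracle: independent binning with hist() on lognormal draws
  set.seed(31)
  x <- rlnorm(500, 8, 1.2)
  tot <- data.table(patient_id = sprintf("Q%d", 1:500), total_cost = x,
                    stratum = episode_stratum(rep(1L, 500)))
  brk <- c(0, 2500, 5000, 10000, 25000, 50000)
  d2 <- cost_frequency_distribution(tot, breaks = brk)
  orc <- hist(x, breaks = c(brk, Inf), right = TRUE, plot = FALSE)$counts
  expect_equal(d2$bins$n, orc[orc > 0])
  expect_equal(sum(d2$bins$n), 500L)
})
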
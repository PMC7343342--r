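#' CPI cost adjustment to reference-year dollars
#'
#' `load_cpi_table()` reads a YAML file of service-year -> multiplier
#' factors restating paid amounts in reference-year (2013) US dollars using
#' the medical-care CPI; the shipped factors are documented placeholders.
#' `adjust_cost()` applies the factors.
#'
#' @param path YAML file with `reference_year` and `factors`.
#' @return `load_cpi_table()`: a named numeric vector (names are years),
#'   with the reference year equal to 1.
#' @export
load_cpi_table <- function(path = system.file("extdata", "cpi_medical.yaml",
                                              package = "vocclaims")) {
  raw <- yaml::read_yaml(path)
  cpi <- unlist(raw$factors)
  cpi <- setNames(as.numeric(cpi), names(raw$factors))
  if (any(cpi <= 0)) stop("CPI factors must be positive")
  ref <- as.character(raw$reference_year)
  if (!ref %in% names(cpi) || abs(cpi[[ref]] - 1) > 1e-12) {
    stop("reference-year CPI factor must be 1.0")
  }
  cpi
}

#' @rdname load_cpi_table
#' @param amount numeric paid amounts in service-year dollars.
#' @param service_year integer service years (recycled against `amount`).
#' @param cpi a [load_cpi_table()] vector.
#' @return `adjust_cost()`: amounts in reference-year dollars.
#' @examples
#' adjust_cost(100, 2013, c(`2013` = 1))
#' @export
adjust_cost <- function(amount, service_year, cpi = load_cpi_table()) {
  yr <- as.character(service_year)
  missing_yr <- setdiff(unique(yr), names(cpi))
  if (length(missing_yr)) {
    stop("cost_analytics: no CPI factor for service year(s): ",
         paste(missing_yr, collapse = ", "))
  }
  amount * unname(cpi[yr])
}

#' SCD-relatedness attribution rules
#'
#' A medical claim is SCD-related iff it carries an SCD diagnosis in any
#' position or a blood-transfusion procedure flag; a pharmacy claim iff its
#' drug class is an SCD-management class (opioids, NSAIDs, hydroxyurea,
#' antibiotics, acetaminophen, folic acid by default).
#'
#' @param dx_codes undotted SCD diagnosis codes.
#' @param drug_classes SCD-management pharmacy classes.
#' @param transfusion_is_scd count transfusion-flagged medical claims as
#'   SCD-related.
#' @return an `scd_rules` list.
#' @export
scd_rules <- function(dx_codes = scd_codes(),
                      drug_classes = c("opioid", "nsaid", "hydroxyurea",
                                       "antibiotic", "acetaminophen",
                                       "folic_acid"),
                      transfusion_is_scd = TRUE) {
  stopifnot(length(dx_codes) > 0)
  structure(list(dx_codes = icd9_strip(dx_codes),
                 drug_classes = drug_classes,
                 transfusion_is_scd = transfusion_is_scd),
            class = "scd_rules")
}

#' @rdname scd_rules
#' @param claims a medical or pharmacy claims data.table (recognized by its
#'   columns).
#' @param rules an `scd_rules` list.
#' @return `is_scd_related()`: logical vector along the rows of `claims`.
#' @export
is_scd_related <- function(claims, rules = scd_rules()) {
  claims <- as.data.table(claims)
  if ("dx_codes" %in% names(claims)) {
    hit <- dx_has_any(claims$dx_codes, rules$dx_codes)
    if (rules$transfusion_is_scd && "is_transfusion" %in% names(claims)) {
      hit <- hit | claims$is_transfusion
    }
    hit
  } else if ("drug_class" %in% names(claims)) {
    claims$drug_class %in% rules$drug_classes
  } else {
    stop("claims table is neither medical (dx_codes) nor pharmacy (drug_class)")
  }
}

## facility types entering the "total" cost row (Table-3 label:
## inpatient + outpatient + LTC + pharmacy)
.total_components <- c("inpatient", "outpatient_hospital", "outpatient_er",
                       "outpatient_office", "outpatient_other",
                       "long_term_care", "pharmacy")

## all follow-up claims of cohort members in one long table:
## patient_id, claim_id, date, end (= date for pharmacy), facility,
## paid_amount, service_year, scd_related
.followup_claims <- function(cohort, bundle, rules = scd_rules()) {
  win <- cohort[, .(patient_id, followup_start, followup_end)]
  med <- bundle$medical[win, on = .(patient_id,
                                    service_start >= followup_start,
                                    service_start <= followup_end),
                        nomatch = NULL,
                        .(patient_id, claim_id = x.claim_id,
                          date = x.service_start, end = x.service_end,
                          facility = x.pos_code,
                          dx_codes = x.dx_codes,
                          is_transfusion = x.is_transfusion,
                          paid_amount = x.paid_amount,
                          service_year = x.service_year)]
  med[, scd_related := is_scd_related(med, rules)]
  med[, c("dx_codes", "is_transfusion") := NULL]
  rx <- bundle$pharmacy[win, on = .(patient_id, fill_date >= followup_start,
                                    fill_date <= followup_end),
                        nomatch = NULL,
                        .(patient_id, claim_id = x.claim_id,
                          date = x.fill_date, end = x.fill_date,
                          facility = "pharmacy",
                          drug_class = x.drug_class,
                          paid_amount = x.paid_amount,
                          service_year = x.service_year)]
  rx[, scd_related := is_scd_related(rx, rules)]
  rx[, drug_class := NULL]
  rbind(med, rx)
}

## per patient-facility utilization: visits (deduplicated claim-days;
## distinct merged admissions for inpatient) and inpatient LOS
.facility_utilization <- function(claims) {
  non_ip <- claims[facility != "inpatient",
                   .(n_visits = uniqueN(date), los_days = NA_integer_),
                   by = .(patient_id, facility)]
  ip <- claims[facility == "inpatient"]
  if (nrow(ip)) {
    stays <- .assign_episode_groups(
      ip[, .(patient_id, claim_id, service_start = date, service_end = end)],
      gap_days = 0L)
    ip_sum <- stays[, .(start = min(service_start), end = max(service_end)),
                    by = .(patient_id, ep)][
      , .(n_visits = .N,
          los_days = sum(as.integer(end - start + 1L))),
      by = patient_id]
    ip_sum[, facility := "inpatient"]
    rbind(non_ip, ip_sum[, .(patient_id, facility, n_visits, los_days)])
  } else {
    non_ip
  }
}

#' Annual all-cause or SCD-related utilization and cost summary
#'
#' For each facility type over the fixed 12-month follow-up: the percent of
#' cohort members with at least one qualifying visit (computed over the
#' whole cohort), mean/SD visit counts (zero for members without a visit),
#' inpatient length of stay, and the mean and median of per-patient summed
#' CPI-adjusted costs. Costs are computed over the costing population only
#' (default fee-for-service members, the plan type with cost data recorded;
#' members without qualifying claims contribute 0). A `"total"` row sums
#' the inpatient, outpatient, long-term-care and pharmacy components per
#' patient before summarization.
#'
#' @param cohort cohort table from [build_cohort()].
#' @param bundle a [claims_bundle()].
#' @param scope `"all_cause"` or `"scd_related"`.
#' @param costing_population `"FFS_only"` (default) or `"all"`.
#' @param cpi a [load_cpi_table()] vector.
#' @param rules an [scd_rules()] list.
#' @return a data.table with one row per facility type plus a `"total"`
#'   row: `facility`, `pct_with_visit`, `mean_visits`, `sd_visits`,
#'   `mean_los`, `sd_los`, `mean_cost`, `median_cost`. Attributes
#'   `n_cohort` and `n_costing` give the population sizes (0 marks an empty
#'   cohort).
#' @export
annual_summary <- function(cohort, bundle,
                           scope = c("all_cause", "scd_related"),
                           costing_population = c("FFS_only", "all"),
                           cpi = load_cpi_table(), rules = scd_rules()) {
  scope <- match.arg(scope)
  costing_population <- match.arg(costing_population)
  cost_ids <- if (costing_population == "FFS_only") {
    cohort[plan_type == "FFS", patient_id]
  } else cohort$patient_id
  empty <- data.table(facility = character(), pct_with_visit = numeric(),
                      mean_visits = numeric(), sd_visits = numeric(),
                      mean_los = numeric(), sd_los = numeric(),
                      mean_cost = numeric(), median_cost = numeric())
  if (!nrow(cohort)) {
    setattr(empty, "n_cohort", 0L)
    setattr(empty, "n_costing", 0L)
    return(empty)
  }
  claims <- .followup_claims(cohort, bundle, rules)
  if (scope == "scd_related") claims <- claims[scd_related == TRUE]
  claims[, adj_cost := adjust_cost(paid_amount, service_year, cpi)]

  util <- .facility_utilization(claims)
  costs <- claims[patient_id %in% cost_ids,
                  .(cost = sum(adj_cost)), by = .(patient_id, facility)]

  n_cohort <- nrow(cohort)
  n_costing <- length(cost_ids)
  rows <- lapply(facility_types(), function(ft) {
    u <- util[facility == ft]
    v <- merge(cohort[, .(patient_id)], u[, .(patient_id, n_visits, los_days)],
               by = "patient_id", all.x = TRUE)
    v[is.na(n_visits), n_visits := 0L]
    cc <- merge(data.table(patient_id = cost_ids),
                costs[facility == ft, .(patient_id, cost)],
                by = "patient_id", all.x = TRUE)
    cc[is.na(cost), cost := 0]
    data.table(
      facility = ft,
      pct_with_visit = 100 * sum(v$n_visits > 0) / n_cohort,
      mean_visits = mean(v$n_visits),
      sd_visits = sd(v$n_visits),
      mean_los = if (ft == "inpatient")
        mean(fifelse(is.na(v$los_days), 0L, v$los_days)) else NA_real_,
      sd_los = if (ft == "inpatient")
        sd(fifelse(is.na(v$los_days), 0L, v$los_days)) else NA_real_,
      mean_cost = if (n_costing) mean(cc$cost) else NA_real_,
      median_cost = if (n_costing) median(cc$cost) else NA_real_
    )
  })
  out <- rbindlist(rows)

  ## total row: per-patient sum of the component facilities, then summarize
  tot <- merge(data.table(patient_id = cost_ids),
               costs[facility %in% .total_components,
                     .(total_cost = sum(cost)), by = patient_id],
               by = "patient_id", all.x = TRUE)
  tot[is.na(total_cost), total_cost := 0]
  out <- rbind(out, data.table(
    facility = "total", pct_with_visit = NA_real_,
    mean_visits = NA_real_, sd_visits = NA_real_,
    mean_los = NA_real_, sd_los = NA_real_,
    mean_cost = if (n_costing) mean(tot$total_cost) else NA_real_,
    median_cost = if (n_costing) median(tot$total_cost) else NA_real_))
  setattr(out, "n_cohort", n_cohort)
  setattr(out, "n_costing", n_costing)
  out[]
}

#' Per-patient SCD-related (or all-cause) annual cost totals
#'
#' The per-patient summed CPI-adjusted follow-up costs over the total-row
#' component facilities, for the costing population; input to the
#' cost-frequency distribution and the stratified summaries.
#'
#' @inheritParams annual_summary
#' @return data.table `patient_id`, `total_cost`.
#' @export
patient_cost_totals <- function(cohort, bundle,
                                scope = c("scd_related", "all_cause"),
                                costing_population = c("FFS_only", "all"),
                                cpi = load_cpi_table(), rules = scd_rules()) {
  scope <- match.arg(scope)
  costing_population <- match.arg(costing_population)
  cost_ids <- if (costing_population == "FFS_only") {
    cohort[plan_type == "FFS", patient_id]
  } else cohort$patient_id
  claims <- .followup_claims(cohort, bundle, rules)
  if (scope == "scd_related") claims <- claims[scd_related == TRUE]
  claims[, adj_cost := adjust_cost(paid_amount, service_year, cpi)]
  tot <- claims[patient_id %in% cost_ids & facility %in% .total_components,
                .(total_cost = sum(adj_cost)), by = patient_id]
  out <- merge(data.table(patient_id = cost_ids), tot,
               by = "patient_id", all.x = TRUE)
  out[is.na(total_cost), total_cost := 0]
  out[]
}

#' SCD-related utilization and costs stratified by episode frequency
#'
#' Splits the cohort by the number of follow-up VOC episodes (0, 1, 2, 3+)
#' and summarizes SCD-related utilization (per-facility visit counts,
#' inpatient length of stay; over all stratum members) and SCD-related
#' CPI-adjusted costs (over fee-for-service members; per-facility and total
#' mean/SD).
#'
#' @param cohort cohort table.
#' @param bundle a [claims_bundle()].
#' @param episodes episode table from [build_episodes()].
#' @param cpi a [load_cpi_table()] vector.
#' @param rules an [scd_rules()] list.
#' @return a list with `strata` (stratum, `n_patients`, `n_ffs`), `hcru`
#'   (stratum x facility visit and LOS statistics), and `costs` (stratum x
#'   facility, including `"total"`, mean/SD of per-patient costs).
#' @export
stratified_summary <- function(cohort, bundle, episodes,
                               cpi = load_cpi_table(), rules = scd_rules()) {
  strata <- count_and_stratify(episodes, cohort)
  strata <- strata[cohort[, .(patient_id, plan_type)], on = "patient_id"]
  claims <- .followup_claims(cohort, bundle, rules)[scd_related == TRUE]
  claims[, adj_cost := adjust_cost(paid_amount, service_year, cpi)]
  util <- .facility_utilization(claims)
  costs <- claims[, .(cost = sum(adj_cost)), by = .(patient_id, facility)]

  sizes <- strata[, .(n_patients = .N, n_ffs = sum(plan_type == "FFS")),
                  keyby = stratum]

  grid <- CJ(patient_id = strata$patient_id, facility = facility_types(),
             unique = TRUE)
  grid <- grid[strata[, .(patient_id, stratum, plan_type)], on = "patient_id"]
  u <- util[grid, on = .(patient_id, facility)]
  u[is.na(n_visits), n_visits := 0L]
  u[facility == "inpatient" & is.na(los_days), los_days := 0L]
  hcru <- u[, .(mean_visits = mean(n_visits), sd_visits = sd(n_visits),
                mean_los = if (facility[1] == "inpatient")
                  mean(los_days) else NA_real_,
                sd_los = if (facility[1] == "inpatient")
                  sd(los_days) else NA_real_),
            keyby = .(stratum, facility)]

  cgrid <- grid[plan_type == "FFS"]
  cc <- costs[cgrid, on = .(patient_id, facility)]
  cc[is.na(cost), cost := 0]
  cost_fac <- cc[, .(mean_cost = mean(cost), sd_cost = sd(cost)),
                 keyby = .(stratum, facility)]
  tot <- cc[facility %in% .total_components,
            .(cost = sum(cost)), by = .(patient_id, stratum)]
  cost_tot <- tot[, .(facility = "total", mean_cost = mean(cost),
                      sd_cost = sd(cost)), keyby = stratum]
  list(strata = sizes[],
       hcru = hcru[],
       costs = rbind(cost_fac, cost_tot)[order(stratum, facility)])
}

#' Costs per VOC episode
#'
#' For each episode of a fee-for-service cohort member: `medical_cost` is
#' the CPI-adjusted sum of all the patient's medical claims, in any setting
#' and with any diagnosis, whose service start lies in the episode window;
#' `scd_pharmacy_cost` is the adjusted sum of SCD-class pharmacy fills in
#' the window; `total_cost` their sum. A per-setting table reports mean/SD
#' episode totals by the episode's assigned care setting.
#'
#' @param episodes episode table from [build_episodes()].
#' @param bundle a [claims_bundle()].
#' @param cohort cohort table (supplies plan type).
#' @param cpi a [load_cpi_table()] vector.
#' @param rules an [scd_rules()] list.
#' @return list with `episode_costs` (one row per FFS episode) and
#'   `by_setting` (setting, `n_episodes`, `mean_cost`, `sd_cost`,
#'   `mean_duration`, plus an `"all"` row).
#' @export
episode_costs <- function(episodes, bundle, cohort,
                          cpi = load_cpi_table(), rules = scd_rules()) {
  ffs <- cohort[plan_type == "FFS", patient_id]
  eps <- episodes[patient_id %in% ffs]
  out <- eps[, .(episode_id, patient_id, setting, start, end, duration_days)]
  if (nrow(eps)) {
    med <- bundle$medical[patient_id %in% ffs,
                          .(patient_id, service_start, paid_amount,
                            service_year)]
    med[, adj_cost := adjust_cost(paid_amount, service_year, cpi)]
    mcost <- med[eps[, .(episode_id, patient_id, start, end)],
                 on = .(patient_id, service_start >= start,
                        service_start <= end),
                 .(episode_id = i.episode_id, adj_cost = x.adj_cost),
                 nomatch = NULL, allow.cartesian = TRUE][
      , .(medical_cost = sum(adj_cost)), by = episode_id]
    rx <- bundle$pharmacy[patient_id %in% ffs]
    rx <- rx[is_scd_related(rx, rules)]
    rx[, adj_cost := adjust_cost(paid_amount, service_year, cpi)]
    pcost <- rx[eps[, .(episode_id, patient_id, start, end)],
                on = .(patient_id, fill_date >= start, fill_date <= end),
                .(episode_id = i.episode_id, adj_cost = x.adj_cost),
                nomatch = NULL, allow.cartesian = TRUE][
      , .(scd_pharmacy_cost = sum(adj_cost)), by = episode_id]
    out[mcost, medical_cost := i.medical_cost, on = "episode_id"]
    out[pcost, scd_pharmacy_cost := i.scd_pharmacy_cost, on = "episode_id"]
    out[is.na(medical_cost), medical_cost := 0]
    out[is.na(scd_pharmacy_cost), scd_pharmacy_cost := 0]
    out[, total_cost := medical_cost + scd_pharmacy_cost]
  } else {
    out[, `:=`(medical_cost = numeric(), scd_pharmacy_cost = numeric(),
               total_cost = numeric())]
  }
  by_setting <- out[, .(n_episodes = .N, mean_cost = mean(total_cost),
                        sd_cost = sd(total_cost),
                        mean_duration = mean(duration_days)),
                    by = setting]
  all_row <- out[, .(setting = "all", n_episodes = .N,
                     mean_cost = mean(total_cost), sd_cost = sd(total_cost),
                     mean_duration = mean(duration_days))]
  list(episode_costs = out[], by_setting = rbind(by_setting, all_row)[])
}

#' Frequency distribution of per-patient SCD-related cost totals
#'
#' Drops zero-total patients (costs possibly not captured), bins the
#' remaining totals on a configurable grid per episode-frequency stratum,
#' and reports each stratum's patient count and maximum total.
#'
#' @param totals data.table with `patient_id`, `total_cost`, `stratum`
#'   (e.g. [patient_cost_totals()] joined to [count_and_stratify()]).
#' @param breaks increasing numeric bin edges; totals beyond the last edge
#'   fall in an overflow bin.
#' @return list with `bins` (stratum, bin label, n) and `summary` (stratum,
#'   n nonzero patients, `max_total`).
#' @export
cost_frequency_distribution <- function(totals,
                                        breaks = c(0, 2500, 5000, 10000,
                                                   25000, 50000, 1e5, 2.5e5,
                                                   5e5, 1e6)) {
  stopifnot(all(diff(breaks) > 0))
  totals <- as.data.table(totals)[total_cost > 0]
  if (!nrow(totals)) {
    return(list(bins = data.table(stratum = factor(levels = levels(
      episode_stratum(0L))), bin = character(), n = integer()),
      summary = data.table(stratum = character(), n = integer(),
                           max_total = numeric())))
  }
  edges <- unique(c(breaks, Inf))
  totals[, bin := cut(total_cost, breaks = edges, include.lowest = TRUE,
                      right = TRUE)]
  bins <- totals[, .N, keyby = .(stratum, bin)]
  setnames(bins, "N", "n")
  summ <- totals[, .(n = .N, max_total = max(total_cost)), keyby = stratum]
  list(bins = bins[], summary = summ[])
}
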
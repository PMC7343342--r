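#' Pipeline run configuration
#'
#' Collects every configurable decision of a full pipeline run so the run
#' log can record it verbatim and a rerun with the same configuration is
#' byte-identical.
#'
#' @param windows a [study_windows()] object.
#' @param gap_days episode merge gap (days), default 3.
#' @param allowable_gap tolerated uncovered enrollment days, default 0.
#' @param costing_population `"FFS_only"` or `"all"`.
#' @param cpi a [load_cpi_table()] vector (or path to a CPI YAML).
#' @param rules an [scd_rules()] list.
#' @param cci_map a [load_cci_map()] object (or path).
#' @param condition_codes a [load_condition_codes()] list (or path).
#' @param cost_breaks bin edges for [cost_frequency_distribution()].
#' @return a `run_config` list.
#' @export
run_config <- function(windows = study_windows(), gap_days = 3L,
                       allowable_gap = 0L,
                       costing_population = c("FFS_only", "all"),
                       cpi = load_cpi_table(), rules = scd_rules(),
                       cci_map = load_cci_map(),
                       condition_codes = load_condition_codes(),
                       cost_breaks = c(0, 2500, 5000, 10000, 25000, 50000,
                                       1e5, 2.5e5, 5e5, 1e6)) {
  if (is.character(cpi)) cpi <- load_cpi_table(cpi)
  if (is.character(cci_map)) cci_map <- load_cci_map(cci_map)
  if (is.character(condition_codes)) {
    condition_codes <- load_condition_codes(condition_codes)
  }
  cfg <- list(windows = windows, gap_days = as.integer(gap_days),
              allowable_gap = as.integer(allowable_gap),
              costing_population = match.arg(costing_population),
              cpi = cpi, rules = rules, cci_map = cci_map,
              condition_codes = condition_codes, cost_breaks = cost_breaks)
  class(cfg) <- "run_config"
  cfg
}

## deterministic md5 of the serialized configuration
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::serializeJSON(config, digits = 12), tf)
  unname(tools::md5sum(tf))
}

#' Demographic summary of a cohort (counts and percentages)
#'
#' Reports the fixed age bands 18-30 / 31-45 / 46-64 / 65+, sex, race,
#' geographic region and plan type, with percentages of the cohort size.
#'
#' @param cohort cohort table from [build_cohort()].
#' @param patients the bundle's patients table.
#' @return data.table `section`, `level`, `n`, `pct` (1 decimal).
#' @export
demographic_table <- function(cohort, patients) {
  dd <- patients[cohort[, .(patient_id, age_at_index)], on = "patient_id"]
  dd[, age_band := cut(age_at_index, c(-Inf, 30, 45, 64, Inf),
                       labels = c("18-30", "31-45", "46-64", "65+"))]
  one <- function(col, section) {
    counts <- dd[, .N, by = .(level = as.character(get(col)))]
    data.table(section = section, level = counts$level, n = counts$N,
               pct = round(100 * counts$N / nrow(dd), 1))
  }
  out <- rbind(one("age_band", "age_group"), one("sex", "sex"),
               one("race", "race_ethnicity"), one("region", "region"),
               one("plan_type", "plan_type"))
  out[]
}

#' Baseline clinical summary (counts and percentages)
#'
#' Summarizes [baseline_profiles()] output: mean/SD Charlson score, the
#' score bands, each condition/medication/utilization flag, the
#' transfusion flag, and baseline VOC burden.
#'
#' @param profiles output of [baseline_profiles()].
#' @return data.table `section`, `level`, `n`, `pct`, `mean`, `sd` (the
#'   statistic columns are filled where they apply).
#' @export
baseline_table <- function(profiles) {
  n <- nrow(profiles)
  num_row <- function(section, level, x) {
    data.table(section = section, level = level, n = NA_integer_,
               pct = NA_real_, mean = mean(x), sd = sd(x))
  }
  flag_rows <- function(section, cols, strip) {
    rbindlist(lapply(cols, function(cc) {
      k <- sum(profiles[[cc]])
      data.table(section = section, level = sub(strip, "", cc), n = k,
                 pct = round(100 * k / n, 1), mean = NA_real_, sd = NA_real_)
    }))
  }
  band <- profiles[, .N, keyby = cci_band]
  out <- rbind(
    num_row("cci", "score", profiles$cci_score),
    data.table(section = "cci_band", level = as.character(band$cci_band),
               n = band$N, pct = round(100 * band$N / n, 1),
               mean = NA_real_, sd = NA_real_),
    flag_rows("condition", grep("^cond_", names(profiles), value = TRUE),
              "^cond_"),
    flag_rows("medication", grep("^med_", names(profiles), value = TRUE),
              "^med_"),
    flag_rows("management", "transfusion_flag", "_flag$"),
    num_row("baseline_voc", "episode_count",
            profiles$baseline_voc_episode_count),
    flag_rows("baseline_voc", c("baseline_voc_inpatient_flag"), ""),
    flag_rows("utilization", grep("^util_", names(profiles), value = TRUE),
              "^util_")
  )
  out[]
}

#' Run the full claims-analysis pipeline
#'
#' Executes read -> cohort -> baseline -> episodes -> cost analytics and
#' returns all report tables plus a machine-readable run log (the verbatim
#' configuration, its md5 hash, and the population size after every
#' stage). Any stage failure aborts with the stage name in the message.
#' Outputs are deterministic: rerunning with the same bundle and
#' configuration reproduces them exactly.
#'
#' @param bundle a [claims_bundle()] (or a directory path readable by
#'   [read_claims_bundle()]).
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every table is written as
#'   CSV whose first line records the configuration hash
#'   (`fread(..., skip = 1)` reads them back), plus `run_log.json`.
#' @return a named list of results: `attrition`, `cohort`, `table1`,
#'   `profiles`, `table2`, `episodes`, `strata`, `table3_all_cause`,
#'   `table3_scd_related`, `strata_summary`, `episode_costs`,
#'   `cost_distribution`, `patient_totals`, and `run_log`.
#' @export
run_pipeline <- function(bundle, config = run_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.character(bundle)) {
    bundle <- stage("claims_model", read_claims_bundle(bundle))
  }
  ch <- stage("cohort_builder", build_cohort(
    bundle, config$windows, allowable_gap = config$allowable_gap))
  cohort <- ch$cohort
  table1 <- stage("report", demographic_table(cohort, bundle$patients))
  profiles <- stage("comorbidity", baseline_profiles(
    cohort, bundle, gap_days = config$gap_days, cci_map = config$cci_map,
    condition_codes = config$condition_codes))
  table2 <- stage("comorbidity", baseline_table(profiles))
  episodes <- stage("episode_builder", build_episodes(
    bundle, cohort, gap_days = config$gap_days))
  strata <- stage("episode_builder", count_and_stratify(episodes, cohort))
  t3_all <- stage("cost_analytics", annual_summary(
    cohort, bundle, "all_cause", config$costing_population, config$cpi,
    config$rules))
  t3_scd <- stage("cost_analytics", annual_summary(
    cohort, bundle, "scd_related", config$costing_population, config$cpi,
    config$rules))
  strat_sum <- stage("cost_analytics", stratified_summary(
    cohort, bundle, episodes, config$cpi, config$rules))
  ep_costs <- stage("cost_analytics", episode_costs(
    episodes, bundle, cohort, config$cpi, config$rules))
  totals <- stage("cost_analytics", patient_cost_totals(
    cohort, bundle, "scd_related", config$costing_population, config$cpi,
    config$rules))
  totals <- totals[strata, on = "patient_id", nomatch = NULL]
  dist <- stage("cost_analytics", cost_frequency_distribution(
    totals, config$cost_breaks))

  run_log <- list(
    config_hash = .config_hash(config),
    n_input_patients = nrow(bundle$patients),
    attrition = ch$attrition,
    n_cohort = nrow(cohort),
    n_ffs = cohort[plan_type == "FFS", .N],
    n_episodes = nrow(episodes),
    strata_sizes = strata[, .N, keyby = stratum]
  )

  res <- list(attrition = ch$attrition, cohort = cohort, table1 = table1,
              profiles = profiles, table2 = table2, episodes = episodes,
              strata = strata, table3_all_cause = t3_all,
              table3_scd_related = t3_scd, strata_summary = strat_sum,
              episode_costs = ep_costs, cost_distribution = dist,
              patient_totals = totals, run_log = run_log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- run_log$config_hash
    emit <- function(dt, name) {
      path <- file.path(out_dir, paste0(name, ".csv"))
      writeLines(paste0("# config_hash=", hash), path)
      fwrite(dt, path, append = TRUE, col.names = TRUE, dateTimeAs = "ISO")
    }
    emit(ch$attrition, "attrition")
    emit(cohort, "cohort")
    emit(table1, "table1_demographics")
    emit(table2, "table2_baseline")
    emit(episodes, "episodes")
    emit(t3_all, "table3_all_cause")
    emit(t3_scd, "table3_scd_related")
    emit(strat_sum$hcru, "strata_hcru")
    emit(strat_sum$costs, "strata_costs")
    emit(ep_costs$episode_costs, "episode_costs")
    emit(ep_costs$by_setting, "episode_costs_by_setting")
    emit(dist$bins, "cost_distribution")
    jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}
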
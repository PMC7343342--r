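## expand "a-b" stem ranges to explicit equal-width stems ("042-044" ->
## "042" "043" "044"); plain stems pass through
.expand_stems <- function(stems) {
  out <- lapply(stems, function(s) {
    if (grepl("^[0-9]+-[0-9]+$", s)) {
      parts <- strsplit(s, "-", fixed = TRUE)[[1]]
      if (nchar(parts[1]) != nchar(parts[2])) {
        stop("range endpoints must have equal width: ", s)
      }
      formatC(seq(as.integer(parts[1]), as.integer(parts[2])),
              width = nchar(parts[1]), flag = "0")
    } else s
  })
  unique(unlist(out))
}

#' Load the Charlson Comorbidity Index condition map
#'
#' Reads a YAML condition map (condition name, integer weight, undotted
#' ICD-9-CM code prefixes with optional `"a-b"` ranges, optional
#' `supersedes` hierarchy link). The shipped default is the Deyo ICD-9-CM
#' adaptation with the original Charlson weights; the file is configuration
#' and can be replaced.
#'
#' @param path YAML file; defaults to the shipped map.
#' @return a `cci_map`: named list of conditions, each with `weight`,
#'   `prefixes` (expanded), and optional `supersedes`.
#' @export
load_cci_map <- function(path = system.file("extdata", "cci_map.yaml",
                                            package = "vocclaims")) {
  raw <- yaml::read_yaml(path)$conditions
  nms <- vapply(raw, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate condition names in CCI map")
  map <- lapply(raw, function(cond) {
    stopifnot(cond$weight %in% c(1L, 2L, 3L, 6L))
    list(weight = as.integer(cond$weight),
         prefixes = .expand_stems(as.character(cond$prefixes)),
         supersedes = cond$supersedes)
  })
  names(map) <- nms
  for (cond in map) {
    if (!is.null(cond$supersedes) && !cond$supersedes %in% nms) {
      stop("supersedes target not in map: ", cond$supersedes)
    }
  }
  structure(map, class = "cci_map")
}

#' Score the Charlson Comorbidity Index from baseline diagnoses
#'
#' Each condition counts at most once, by prefix match of any diagnosis in
#' any position across the supplied claims; hierarchical exclusions
#' (`supersedes`) drop the milder condition when the severe one is present.
#' The score is the sum of the weights of the remaining conditions.
#'
#' @param dx_strings character vector of `;`-separated undotted diagnosis
#'   strings (one element per claim), e.g. `bundle$medical$dx_codes`
#'   restricted to the baseline window.
#' @param map a [load_cci_map()] object.
#' @return list with `score` (integer), `band` (factor `"0"`, `"1"`,
#'   `"2-3"`, `"4+"`), and `conditions` (character vector of the conditions
#'   counted).
#' @export
cci_score <- function(dx_strings, map = load_cci_map()) {
  present <- names(map)[vapply(map, function(cond) {
    any(dx_has_prefix(dx_strings, cond$prefixes))
  }, NA)]
  dropped <- unlist(lapply(map[present], `[[`, "supersedes"))
  present <- setdiff(present, dropped)
  score <- sum(vapply(map[present], `[[`, 0L, "weight"))
  list(score = as.integer(score), band = cci_band(score),
       conditions = present)
}

#' @describeIn cci_score map scores to the reporting bands 0 / 1 / 2-3 / 4+.
#' @param score integer vector of CCI scores.
#' @export
cci_band <- function(score) {
  cut(score, breaks = c(-Inf, 0, 1, 3, Inf),
      labels = c("0", "1", "2-3", "4+"))
}

#' Load the baseline comorbid-condition code stems
#'
#' @param path YAML file mapping condition flag names to undotted ICD-9-CM
#'   stems (ranges allowed); defaults to the shipped list.
#' @return named list of expanded prefix vectors.
#' @export
load_condition_codes <- function(path = system.file(
  "extdata", "condition_codes.yaml", package = "vocclaims")) {
  lapply(yaml::read_yaml(path)$conditions, function(x) {
    .expand_stems(as.character(x))
  })
}

#' Baseline clinical profiles for a cohort
#'
#' Characterizes each cohort member over the 6-month baseline window only:
#' Charlson score and band, comorbid-condition flags, SCD medication flags
#' (one per pharmacy drug class), blood-transfusion flag, baseline VOC
#' episode count (built with the same gap-merge rule as follow-up
#' episodes), a flag for any baseline VOC episode in the inpatient setting,
#' and per-facility-type all-cause utilization flags.
#'
#' @param cohort cohort table from [build_cohort()].
#' @param bundle a [claims_bundle()].
#' @param gap_days episode gap rule for baseline VOC episodes (default 3).
#' @param cci_map a [load_cci_map()] object.
#' @param condition_codes a [load_condition_codes()] list.
#' @param hierarchy a [setting_hierarchy()].
#' @return a data.table, one row per cohort member: `cci_score`,
#'   `cci_band`, `cond_*` flags, `med_*` flags, `transfusion_flag`,
#'   `baseline_voc_episode_count`, `baseline_voc_inpatient_flag`, and
#'   `util_*` facility flags.
#' @export
baseline_profiles <- function(cohort, bundle, gap_days = 3L,
                              cci_map = load_cci_map(),
                              condition_codes = load_condition_codes(),
                              hierarchy = setting_hierarchy()) {
  base_med <- bundle$medical[cohort[, .(patient_id, baseline_start,
                                        baseline_end)],
                             on = .(patient_id,
                                    service_start >= baseline_start,
                                    service_start <= baseline_end),
                             nomatch = NULL,
                             .(patient_id, claim_id = x.claim_id,
                               service_start = x.service_start,
                               service_end = x.service_end,
                               dx_codes = x.dx_codes, pos_code = x.pos_code,
                               is_transfusion = x.is_transfusion)]
  base_rx <- bundle$pharmacy[cohort[, .(patient_id, baseline_start,
                                        baseline_end)],
                             on = .(patient_id, fill_date >= baseline_start,
                                    fill_date <= baseline_end),
                             nomatch = NULL,
                             .(patient_id, drug_class = x.drug_class)]

  out <- cohort[, .(patient_id)]

  ## CCI per patient
  cci <- base_med[, {
    sc <- cci_score(dx_codes, cci_map)
    .(cci_score = sc$score)
  }, by = patient_id]
  out[cci, cci_score := i.cci_score, on = "patient_id"]
  out[is.na(cci_score), cci_score := 0L]
  out[, cci_band := cci_band(cci_score)]

  ## comorbid-condition flags
  for (nm in names(condition_codes)) {
    hit <- base_med[dx_has_prefix(dx_codes, condition_codes[[nm]]),
                    unique(patient_id)]
    set(out, j = paste0("cond_", nm), value = out$patient_id %in% hit)
  }

  ## medication flags per drug class
  for (cl in .enum_levels$drug_class) {
    hit <- base_rx[drug_class == cl, unique(patient_id)]
    set(out, j = paste0("med_", cl), value = out$patient_id %in% hit)
  }

  ## transfusion flag
  out[, transfusion_flag :=
        patient_id %in% base_med[is_transfusion == TRUE, unique(patient_id)]]

  ## baseline VOC episodes (same merge rule as follow-up)
  base_voc <- identify_voc_claims(base_med)
  if (nrow(base_voc)) {
    base_eps <- .episode_table(base_voc, gap_days, hierarchy)
    cnt <- base_eps[, .(baseline_voc_episode_count = .N,
                        baseline_voc_inpatient_flag =
                          any(setting == "inpatient")),
                    by = patient_id]
    out[cnt, `:=`(baseline_voc_episode_count = i.baseline_voc_episode_count,
                  baseline_voc_inpatient_flag =
                    i.baseline_voc_inpatient_flag),
        on = "patient_id"]
  }
  if (!"baseline_voc_episode_count" %in% names(out)) {
    out[, baseline_voc_episode_count := NA_integer_]
    out[, baseline_voc_inpatient_flag := NA]
  }
  out[is.na(baseline_voc_episode_count), baseline_voc_episode_count := 0L]
  out[is.na(baseline_voc_inpatient_flag), baseline_voc_inpatient_flag := FALSE]

  ## all-cause utilization flags per facility type
  for (ft in setdiff(facility_types(), "pharmacy")) {
    hit <- base_med[pos_code == ft, unique(patient_id)]
    set(out, j = paste0("util_", ft), value = out$patient_id %in% hit)
  }
  out[, util_pharmacy := patient_id %in% base_rx$patient_id]
  out[]
}
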
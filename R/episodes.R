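#' Identify VOC-coded medical claims
#'
#' Returns the claims whose diagnosis string contains, in any position, one
#' of the VOC codes (default 282.42, 282.62, 282.64, 282.69). Input order is
#' preserved.
#'
#' @param claims a medical-claims data.table.
#' @param code_set undotted VOC codes, default [voc_codes()].
#' @return the qualifying subset of `claims`.
#' @export
identify_voc_claims <- function(claims, code_set = voc_codes()) {
  claims <- as.data.table(claims)
  if (!nrow(claims)) return(claims)
  claims[dx_has_any(dx_codes, code_set)]
}

## core gap-merge: assign an episode group to sorted claims of one or many
## patients. A claim joins the running episode iff its service_start is at
## most `gap_days` after the episode's running end (max service_end so far);
## otherwise it opens a new episode. Equivalent to connected components of
## the "interval separation <= gap_days" graph.
.assign_episode_groups <- function(claims, gap_days) {
  claims <- copy(claims)
  setorder(claims, patient_id, service_start, service_end, claim_id)
  claims[, run_end := shift(cummax(as.integer(service_end))),
         by = patient_id]
  claims[, new_ep := is.na(run_end) |
           as.integer(service_start) - run_end > gap_days]
  claims[, ep := cumsum(new_ep), by = patient_id]
  claims[, c("run_end", "new_ep") := NULL]
  claims
}

#' Merge one patient's VOC claims into episodes with a gap rule
#'
#' Claims are sorted by (`service_start`, `service_end`, `claim_id`); a
#' claim joins the current episode iff its start is no more than `gap_days`
#' days after the episode's running end (the maximum `service_end` seen),
#' otherwise it starts a new episode. With the default `gap_days = 3`,
#' single-day claims on day 1 and day 4 merge, day 1 and day 5 do not.
#' Episode duration is inclusive (`end - start + 1`).
#'
#' @param voc_claims VOC-coded claims of a single patient.
#' @param gap_days maximum mergeable separation in days (default 3).
#' @param hierarchy a [setting_hierarchy()] for setting assignment, or
#'   `NULL` to skip.
#' @return a data.table of episodes in chronological order: `patient_id`,
#'   `episode_index`, `start`, `end`, `duration_days`, `n_claims`,
#'   `member_claim_ids` (`;`-separated), and `setting` when a hierarchy is
#'   given.
#' @export
merge_into_episodes <- function(voc_claims, gap_days = 3L,
                                hierarchy = setting_hierarchy()) {
  voc_claims <- as.data.table(voc_claims)
  if (nrow(voc_claims) && uniqueN(voc_claims$patient_id) > 1L) {
    stop("merge_into_episodes() expects claims of a single patient; ",
         "use build_episodes() for a full bundle")
  }
  .episode_table(voc_claims, gap_days, hierarchy)
}

## shared episode aggregation (any number of patients)
.episode_table <- function(voc_claims, gap_days, hierarchy) {
  stopifnot(gap_days >= 0L)
  empty <- data.table(patient_id = character(), episode_index = integer(),
                      start = as.IDate(integer()), end = as.IDate(integer()),
                      duration_days = integer(), n_claims = integer(),
                      member_claim_ids = character(), setting = character())
  if (!nrow(voc_claims)) return(empty)
  grouped <- .assign_episode_groups(voc_claims, gap_days)
  eps <- grouped[, .(start = min(service_start),
                     end = max(service_end),
                     n_claims = .N,
                     member_claim_ids = paste(claim_id, collapse = ";"),
                     setting = if (is.null(hierarchy)) NA_character_ else
                       classify_setting(pos_code, hierarchy)),
                 by = .(patient_id, episode_index = ep)]
  set(eps, j = "start", value = as.IDate(eps$start))
  set(eps, j = "end", value = as.IDate(eps$end))
  eps[, duration_days := as.integer(end - start + 1L)]
  eps[, episode_id := paste0(patient_id, "-E", episode_index)]
  setcolorder(eps, c("patient_id", "episode_id", "episode_index", "start",
                     "end", "duration_days", "n_claims", "member_claim_ids",
                     "setting"))
  setorder(eps, patient_id, start)
  eps[]
}

#' Build post-index VOC episodes for a whole cohort
#'
#' Restricts medical claims to each cohort member's claims with
#' `service_start` on or after the index date, selects VOC-coded claims,
#' merges them into episodes with the gap rule, and assigns each episode a
#' care setting by the inpatient > ER > outpatient > office > other
#' hierarchy.
#'
#' @param bundle a [claims_bundle()].
#' @param cohort the `cohort` table from [build_cohort()].
#' @param gap_days maximum mergeable separation in days (default 3).
#' @param code_set undotted VOC codes.
#' @param hierarchy a [setting_hierarchy()].
#' @return an episode data.table (see [merge_into_episodes()]).
#' @export
build_episodes <- function(bundle, cohort, gap_days = 3L,
                           code_set = voc_codes(),
                           hierarchy = setting_hierarchy()) {
  med <- bundle$medical[patient_id %in% cohort$patient_id]
  med <- med[cohort[, .(patient_id, index_date)], on = "patient_id",
             nomatch = NULL][service_start >= index_date]
  med[, index_date := NULL]
  .episode_table(identify_voc_claims(med, code_set), gap_days, hierarchy)
}

#' Count follow-up episodes and assign the frequency stratum
#'
#' Counts the episodes whose start date lies inside each patient's
#' follow-up window and maps the count to the 0 / 1 / 2 / 3+ stratum.
#' Patients with no episodes get count 0.
#'
#' @param episodes an episode table from [build_episodes()].
#' @param cohort the cohort table (supplies `followup_start`/`followup_end`
#'   per patient).
#' @return the cohort's patients with `n_episodes` and `stratum` (factor
#'   with levels `"0"`, `"1"`, `"2"`, `"3+"`).
#' @export
count_and_stratify <- function(episodes, cohort) {
  counts <- episodes[cohort, on = .(patient_id, start >= followup_start,
                                    start <= followup_end),
                     .(n_episodes = sum(!is.na(x.start))),
                     by = .EACHI][, .(patient_id, n_episodes)]
  out <- cohort[, .(patient_id)][counts, on = "patient_id"]
  out[is.na(n_episodes), n_episodes := 0L]
  out[, stratum := episode_stratum(n_episodes)]
  out[]
}

#' @describeIn count_and_stratify map episode counts to the stratum factor.
#' @param n integer episode counts.
#' @export
episode_stratum <- function(n) {
  factor(fifelse(n >= 3L, "3+", as.character(n)),
         levels = c("0", "1", "2", "3+"))
}
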
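#' Facility types, care settings and the classification hierarchy
#'
#' Claims carry a place-of-service category (`pos_code`) drawn from the ten
#' facility types used in the annual utilization/cost tables. For per-episode
#' analysis every facility type maps onto one of five care settings, and an
#' episode touching several settings is assigned the highest-priority one in
#' the order inpatient > ER > outpatient > office > other. Outpatient
#' absorbs outpatient hospital, ambulatory surgery center and long-term
#' care/nursing facility; office covers clinic-type places of service; every
#' remaining facility type falls into "other".
#'
#' @return `facility_types()` and `care_settings()` return character vectors
#'   (the latter in priority order, highest first). `setting_hierarchy()`
#'   returns a list with elements `priority` and `pos_to_setting` (named map
#'   facility type -> setting).
#' @examples
#' setting_hierarchy()$pos_to_setting[["long_term_care"]]
#' @export
facility_types <- function() {
  c("inpatient", "outpatient_hospital", "outpatient_er", "outpatient_office",
    "outpatient_other", "ambulatory_surgery_center", "lab", "hospice",
    "long_term_care", "pharmacy")
}

#' @rdname facility_types
#' @export
care_settings <- function() {
  c("inpatient", "er", "outpatient", "office", "other")
}

#' @rdname facility_types
#' @export
setting_hierarchy <- function() {
  list(
    priority = care_settings(),
    pos_to_setting = c(
      inpatient                 = "inpatient",
      outpatient_er             = "er",
      outpatient_hospital       = "outpatient",
      ambulatory_surgery_center = "outpatient",
      long_term_care            = "outpatient",
      outpatient_office         = "office",
      outpatient_other          = "other",
      lab                       = "other",
      hospice                   = "other",
      pharmacy                  = "other"
    )
  )
}

#' Classify an episode's care setting from its member claims
#'
#' Maps each member claim's place-of-service category to one of the five
#' care settings and returns the highest-priority setting present.
#'
#' @param pos_codes character vector of facility-type codes of the member
#'   claims (at least one).
#' @param hierarchy a [setting_hierarchy()] list.
#' @return a single setting string.
#' @examples
#' classify_setting(c("outpatient_er", "inpatient"))
#' classify_setting(c("long_term_care", "outpatient_office"))
#' @export
classify_setting <- function(pos_codes, hierarchy = setting_hierarchy()) {
  if (length(pos_codes) == 0L) stop("episode has no member claims")
  unmapped <- setdiff(unique(pos_codes), names(hierarchy$pos_to_setting))
  if (length(unmapped)) {
    stop("unmapped place-of-service code(s): ", paste(unmapped, collapse = ", "))
  }
  settings <- hierarchy$pos_to_setting[pos_codes]
  hierarchy$priority[min(match(settings, hierarchy$priority))]
}
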
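#' ICD-9-CM code utilities and the SCD/VOC code sets
#'
#' Diagnosis codes are stored internally in undotted MAX-style form
#' (`"28262"`, `"V434"`); accessors accept dotted input. Multiple diagnoses
#' on one claim line are kept as a single `;`-separated string in diagnosis
#' position order (position 1 = primary).
#'
#' @param codes character vector of ICD-9-CM codes, dotted or undotted.
#' @return `icd9_strip()` returns undotted upper-case codes; `icd9_dotted()`
#'   re-inserts the decimal point (after the third character, fourth for
#'   E-codes).
#' @examples
#' icd9_strip("282.62")
#' icd9_dotted("28262")
#' @export
icd9_strip <- function(codes) {
  toupper(gsub(".", "", trimws(as.character(codes)), fixed = TRUE))
}

#' @rdname icd9_strip
#' @export
icd9_dotted <- function(codes) {
  codes <- icd9_strip(codes)
  pos <- ifelse(startsWith(codes, "E"), 4L, 3L)
  out <- codes
  long <- !is.na(codes) & nchar(codes) > pos
  out[long] <- paste0(substr(codes[long], 1L, pos[long]),
                      ".", substring(codes[long], pos[long] + 1L))
  out
}

#' @describeIn icd9_strip the SCD identification code set
#'   (282.41, 282.42, 282.60-282.69), undotted.
#' @export
scd_codes <- function() {
  c("28241", "28242", paste0("2826", 0:9))
}

#' @describeIn icd9_strip the VOC code subset (282.42, 282.62, 282.64,
#'   282.69), undotted.
#' @export
voc_codes <- function() {
  c("28242", "28262", "28264", "28269")
}

## ---- multi-diagnosis string helpers (internal) ----

dx_join <- function(x) vapply(x, paste, "", collapse = ";")

dx_split <- function(x) strsplit(x, ";", fixed = TRUE)

## TRUE where any diagnosis position holds one of `codes` exactly
dx_has_any <- function(dx, codes) {
  codes <- icd9_strip(codes)
  pat <- paste0("(^|;)(", paste(codes, collapse = "|"), ")(;|$)")
  grepl(pat, dx)
}

## TRUE where any diagnosis position starts with one of `stems`
dx_has_prefix <- function(dx, stems) {
  stems <- icd9_strip(stems)
  pat <- paste0("(^|;)(", paste(stems, collapse = "|"), ")")
  grepl(pat, dx)
}
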
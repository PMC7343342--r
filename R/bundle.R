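## Canonical table layouts for the four input tables. Dates are ISO-8601 in
## files and data.table::IDate (integer days) internally; all date windows in
## the package are closed intervals [start, end].

.table_columns <- list(
  patients = c("patient_id", "birth_date", "sex", "race", "region",
               "plan_type", "death_date", "clinical_trial_flag"),
  medical = c("claim_id", "patient_id", "service_start", "service_end",
              "dx_codes", "pos_code", "is_transfusion", "paid_amount",
              "service_year"),
  pharmacy = c("claim_id", "patient_id", "fill_date", "drug_class",
               "paid_amount", "service_year"),
  enrollment = c("patient_id", "span_start", "span_end", "medical_coverage",
                 "pharmacy_coverage")
)

.enum_levels <- list(
  sex = c("male", "female"),
  race = c("white", "black", "hispanic", "other", "unknown"),
  region = c("northeast", "south", "west", "north_central"),
  plan_type = c("FFS", "managed_care"),
  drug_class = c("antibiotic", "acetaminophen", "folic_acid", "opioid",
                 "nsaid", "hydroxyurea", "other")
)

#' Assemble and validate a claims table bundle
#'
#' A bundle holds the four analysis inputs as `data.table`s with canonical
#' column names: `patients`, `medical` (one claim line per row, diagnoses as
#' a `;`-separated undotted ICD-9-CM string in position order), `pharmacy`,
#' and `enrollment`. Type and range invariants (dates ordered, non-negative
#' paid amounts, closed enumerations, unique ids) are enforced on
#' construction.
#'
#' @param patients,medical,pharmacy,enrollment data.frames with the
#'   canonical columns (see Details in [read_claims_bundle()]).
#' @param validate run invariant checks (default `TRUE`).
#' @return an object of class `claims_bundle`: a named list of the four
#'   data.tables.
#' @export
claims_bundle <- function(patients, medical, pharmacy, enrollment,
                          validate = TRUE) {
  b <- list(
    patients = .coerce_table(as.data.table(patients), "patients"),
    medical = .coerce_table(as.data.table(medical), "medical"),
    pharmacy = .coerce_table(as.data.table(pharmacy), "pharmacy"),
    enrollment = .coerce_table(as.data.table(enrollment), "enrollment")
  )
  class(b) <- "claims_bundle"
  if (validate) {
    diags <- validate_bundle(b)
    if (nrow(diags)) {
      stop("bundle invariant violations:\n",
           paste(utils::capture.output(print(diags)), collapse = "\n"))
    }
  }
  b
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in names(.table_columns)) {
    cat(sprintf("  %-10s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

## coerce columns to internal types; assumes canonical names already
.coerce_table <- function(dt, table) {
  cols <- .table_columns[[table]]
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(sprintf("table '%s' is missing required column(s): %s",
                 table, paste(missing, collapse = ", ")))
  }
  dt <- dt[, ..cols]
  date_cols <- intersect(cols, c("birth_date", "death_date", "service_start",
                                 "service_end", "fill_date", "span_start",
                                 "span_end"))
  for (cc in date_cols) set(dt, j = cc, value = as.IDate(dt[[cc]]))
  for (cc in intersect(cols, c("clinical_trial_flag", "is_transfusion",
                               "medical_coverage", "pharmacy_coverage"))) {
    set(dt, j = cc, value = as.logical(dt[[cc]]))
  }
  for (cc in intersect(cols, c("paid_amount"))) {
    set(dt, j = cc, value = as.numeric(dt[[cc]]))
  }
  for (cc in intersect(cols, c("service_year"))) {
    set(dt, j = cc, value = as.integer(dt[[cc]]))
  }
  char_cols <- setdiff(cols, c(date_cols, "clinical_trial_flag",
                               "is_transfusion", "medical_coverage",
                               "pharmacy_coverage", "paid_amount",
                               "service_year"))
  for (cc in char_cols) set(dt, j = cc, value = as.character(dt[[cc]]))
  if ("dx_codes" %in% cols) {
    set(dt, j = "dx_codes",
        value = vapply(dx_split(dt$dx_codes),
                       function(v) paste(icd9_strip(v), collapse = ";"), ""))
  }
  dt[]
}

## Row-level invariant diagnostics: data.table(table, row, message)
.table_diagnostics <- function(dt, table) {
  bad <- list()
  note <- function(rows, msg) {
    if (length(rows)) {
      bad[[length(bad) + 1L]] <<- data.table(table = table, row = rows,
                                             message = msg)
    }
  }
  if (table == "patients") {
    note(which(is.na(dt$patient_id) | dt$patient_id == ""),
         "missing patient_id")
    note(which(duplicated(dt$patient_id)), "duplicate patient_id")
    note(which(is.na(dt$birth_date)), "unparseable birth_date")
    note(which(!is.na(dt$death_date) & dt$death_date < dt$birth_date),
         "death_date before birth_date")
    for (cc in c("sex", "race", "region", "plan_type")) {
      note(which(!dt[[cc]] %in% .enum_levels[[cc]]),
           sprintf("invalid %s value", cc))
    }
  } else if (table == "medical") {
    note(which(duplicated(dt$claim_id)), "duplicate claim_id")
    note(which(is.na(dt$service_start) | is.na(dt$service_end)),
         "unparseable service date")
    note(which(dt$service_end < dt$service_start),
         "service_end before service_start")
    note(which(is.na(dt$dx_codes) | dt$dx_codes == ""), "empty dx_codes")
    note(which(!dt$pos_code %in% facility_types()), "invalid pos_code")
    note(which(is.na(dt$paid_amount) | dt$paid_amount < 0),
         "missing or negative paid_amount")
  } else if (table == "pharmacy") {
    note(which(duplicated(dt$claim_id)), "duplicate claim_id")
    note(which(is.na(dt$fill_date)), "unparseable fill_date")
    note(which(!dt$drug_class %in% .enum_levels$drug_class),
         "invalid drug_class")
    note(which(is.na(dt$paid_amount) | dt$paid_amount < 0),
         "missing or negative paid_amount")
  } else if (table == "enrollment") {
    note(which(is.na(dt$span_start) | is.na(dt$span_end)),
         "unparseable span date")
    note(which(dt$span_end < dt$span_start), "span_end before span_start")
  }
  if (length(bad)) rbindlist(bad) else
    data.table(table = character(), row = integer(), message = character())
}

#' @describeIn claims_bundle run all row-level invariant checks; returns a
#'   diagnostics data.table (`table`, `row`, `message`), empty when clean.
#' @param bundle a `claims_bundle`.
#' @export
validate_bundle <- function(bundle) {
  rbindlist(lapply(names(.table_columns), function(nm) {
    .table_diagnostics(bundle[[nm]], nm)
  }))
}

#' Read a claims table bundle from delimited text files
#'
#' Reads the four canonical tables (`patients`, `medical`, `pharmacy`,
#' `enrollment`) from delimited files with a mandatory header row, parses
#' ISO-8601 dates, normalizes diagnosis codes to undotted form, and enforces
#' all row invariants. A missing required column is always a hard error
#' naming the column; row-level problems (unparseable dates, negative costs,
#' reversed intervals, bad enum values) either abort (`on_error = "stop"`)
#' or drop the offending rows (`on_error = "skip"`), in which case the
#' returned bundle carries the diagnostics table in `attr(, "rejected")`.
#'
#' @param paths either a directory containing `patients.csv`, `medical.csv`,
#'   `pharmacy.csv`, `enrollment.csv`, or a named character vector/list with
#'   those four names giving explicit file paths.
#' @param sep field delimiter (`","` default, `"\t"` for TSV).
#' @param schema optional header-mapping config: a YAML/JSON file path or a
#'   named list, `list(<table> = c(custom_header = "canonical_name", ...))`,
#'   applied before validation.
#' @param on_error `"stop"` (default) or `"skip"`.
#' @return a validated [claims_bundle()].
#' @export
read_claims_bundle <- function(paths, sep = ",", schema = NULL,
                               on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    paths <- setNames(file.path(paths, paste0(names(.table_columns), ".csv")),
                      names(.table_columns))
  }
  paths <- as.list(paths)
  missing_tabs <- setdiff(names(.table_columns), names(paths))
  if (length(missing_tabs)) {
    stop("no path given for table(s): ", paste(missing_tabs, collapse = ", "))
  }
  if (is.character(schema) && length(schema) == 1L) {
    schema <- yaml::read_yaml(schema)
  }
  raw <- list()
  for (nm in names(.table_columns)) {
    if (!file.exists(paths[[nm]])) stop("file not found: ", paths[[nm]])
    dt <- fread(paths[[nm]], sep = sep, colClasses = "character",
                header = TRUE, na.strings = c("", "NA"))
    if (!is.null(schema[[nm]])) {
      m <- schema[[nm]]
      setnames(dt, old = names(m), new = unlist(m), skip_absent = TRUE)
    }
    missing <- setdiff(.table_columns[[nm]], names(dt))
    if (length(missing)) {
      stop(sprintf("table '%s' (%s) is missing required column(s): %s",
                   nm, paths[[nm]], paste(missing, collapse = ", ")))
    }
    raw[[nm]] <- .coerce_table(dt, nm)
  }
  diags <- rbindlist(lapply(names(raw), function(nm) {
    .table_diagnostics(raw[[nm]], nm)
  }))
  if (nrow(diags) && on_error == "stop") {
    stop("invalid rows on load:\n",
         paste(utils::capture.output(print(diags)), collapse = "\n"))
  }
  if (nrow(diags)) {
    for (nm in unique(diags$table)) {
      drop <- unique(diags[table == nm, row])
      raw[[nm]] <- raw[[nm]][-drop]
    }
  }
  b <- claims_bundle(raw$patients, raw$medical, raw$pharmacy, raw$enrollment,
                     validate = FALSE)
  setattr(b, "rejected", diags)
  b
}

#' Write a claims bundle to delimited text files
#'
#' Inverse of [read_claims_bundle()]: writes the four tables with ISO-8601
#' dates so that a write/read round trip reproduces the bundle exactly.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @param sep field delimiter.
#' @return invisibly, the named vector of file paths written.
#' @export
write_claims_bundle <- function(bundle, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(names(.table_columns), ".csv")),
                    names(.table_columns))
  for (nm in names(.table_columns)) {
    fwrite(bundle[[nm]], paths[[nm]], sep = sep, dateTimeAs = "ISO",
           logical01 = FALSE)
  }
  invisible(paths)
}

#' Merge overlapping or abutting enrollment spans
#'
#' Per patient and coverage-flag combination, overlapping and abutting
#' (gap 0) spans are merged into maximal spans; the set of covered days is
#' unchanged and the result is sorted. Idempotent.
#'
#' @param spans an enrollment data.table (canonical columns).
#' @return a normalized enrollment data.table.
#' @export
normalize_enrollment <- function(spans) {
  spans <- .coerce_table(as.data.table(spans), "enrollment")
  if (!nrow(spans)) return(spans)
  setorder(spans, patient_id, medical_coverage, pharmacy_coverage,
           span_start, span_end)
  spans[, run_end := cummax(as.integer(span_end)),
        by = .(patient_id, medical_coverage, pharmacy_coverage)]
  spans[, new_ep := {
    prev <- shift(run_end)
    is.na(prev) | as.integer(span_start) > prev + 1L
  }, by = .(patient_id, medical_coverage, pharmacy_coverage)]
  spans[, ep := cumsum(new_ep),
        by = .(patient_id, medical_coverage, pharmacy_coverage)]
  out <- spans[, .(span_start = min(span_start), span_end = max(span_end)),
               by = .(patient_id, medical_coverage, pharmacy_coverage, ep)]
  out[, ep := NULL]
  set(out, j = "span_start", value = as.IDate(out$span_start))
  set(out, j = "span_end", value = as.IDate(out$span_end))
  setcolorder(out, .table_columns$enrollment)
  setorder(out, patient_id, span_start)
  out[]
}
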
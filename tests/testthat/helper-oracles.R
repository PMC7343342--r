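library(data.table)

## Brute-force episode oracle: connected components (union-find) of the
## graph on claims with an edge where the interval separation is <= gap.
## Independent of the sequential sweep used by the package.
oracle_episodes <- function(starts, ends, gap) {
  n <- length(starts)
  if (n == 0L) {
    return(data.table(start = integer(), end = integer(),
                      n_claims = integer()))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sep <- max(starts[i], starts[j]) - min(ends[i], ends[j])
        if (sep <= gap) parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  dt <- data.table(comp = comp, s = starts, e = ends)
  out <- dt[, .(start = min(s), end = max(e), n_claims = .N),
            by = comp][order(start)]
  out[, comp := NULL]
  out[]
}

## Random single-patient VOC claim set: up to `max_claims` claims with
## start offsets within a ~30-day span and durations 0-5 days.
random_claim_set <- function(n_claims, base = as.IDate("2010-06-01")) {
  starts <- sample(0:30, n_claims, replace = TRUE)
  durs <- sample(0:5, n_claims, replace = TRUE)
  data.table(
    claim_id = sprintf("X%03d", seq_len(n_claims)),
    patient_id = "PX",
    service_start = base + starts,
    service_end = base + starts + durs,
    dx_codes = "28262",
    pos_code = sample(c("inpatient", "outpatient_er", "outpatient_hospital",
                        "outpatient_office"), n_claims, replace = TRUE),
    is_transfusion = FALSE,
    paid_amount = 1,
    service_year = 2010L
  )
}

## Minimal single-patient bundle builder for cost tests
one_patient_bundle <- function(medical, pharmacy = NULL,
                               plan_type = "FFS",
                               index = "2013-01-10") {
  if (is.null(pharmacy)) {
    pharmacy <- data.table(claim_id = character(), patient_id = character(),
                           fill_date = as.IDate(integer()),
                           drug_class = character(),
                           paid_amount = numeric(),
                           service_year = integer())
  }
  patients <- data.table(patient_id = "P1",
                         birth_date = as.IDate("1980-01-01"),
                         sex = "female", race = "black",
                         region = "northeast", plan_type = plan_type,
                         death_date = as.IDate(NA),
                         clinical_trial_flag = FALSE)
  enrollment <- data.table(patient_id = "P1",
                           span_start = as.IDate("2009-01-01"),
                           span_end = as.IDate("2013-12-31"),
                           medical_coverage = TRUE,
                           pharmacy_coverage = TRUE)
  claims_bundle(patients, medical, pharmacy, enrollment)
}

unit_cpi <- setNames(rep(1, 5), 2009:2013)

## Hand-scored Charlson examples used by both the unit and acceptance
## suites: diagnosis strings, expected score, expected band. Scores are
## hand sums over the shipped Deyo map with the supersedes hierarchy.
cci_cases <- list(
  list(dx = character(),            score = 0L, band = "0"),   # nothing
  list(dx = "41001",                score = 1L, band = "1"),   # MI
  list(dx = c("41001", "412"),      score = 1L, band = "1"),   # MI once
  list(dx = "25000",                score = 1L, band = "1"),   # diabetes
  list(dx = c("25000", "25040"),    score = 2L, band = "2-3"), # compl. supersedes
  list(dx = c("4280", "49320"),     score = 2L, band = "2-3"), # CHF + pulm
  list(dx = c("4280", "25000", "7140"), score = 3L, band = "2-3"),
  list(dx = c("1970", "1628"),      score = 6L, band = "4+"),  # metastatic only
  list(dx = c("5712", "5722"),      score = 3L, band = "2-3"), # severe liver supersedes mild
  list(dx = "042",                  score = 6L, band = "4+"),  # AIDS
  list(dx = c("3441", "5853", "V434"), score = 5L, band = "4+"),
  list(dx = c("4280;25000", "7140", "2504"), score = 4L, band = "4+")
)
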
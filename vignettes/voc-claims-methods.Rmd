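---
title: "Methods: VOC episode construction and cost analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VOC episode construction and cost analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocclaims)
library(data.table)
```

# The analysis

This package measures the economic burden of vaso-occlusive crisis (VOC)
in adult sickle cell disease (SCD) from administrative claims. The
quantity of interest is not a regression coefficient but a set of
carefully defined descriptive summaries: annual all-cause and SCD-related
utilization and costs by facility type, the same stratified by VOC episode
frequency, and the cost of an individual VOC episode by care setting. The
methodological substance is in the definitions — who enters the cohort,
what counts as one episode, which setting an episode belongs to, and which
dollars are attributed where. Each definition is implemented as a small,
separately testable function with its parameters exposed.

# Cohort eligibility

A patient enters the cohort if they have:

1. an **index event** — the earliest medical claim carrying an SCD
   diagnosis (ICD-9-CM 282.41, 282.42, 282.60–282.69, any diagnosis
   position) inside the identification period, 2009-07-01 to 2012-12-31
   by default;
2. **age ≥ 18** at index, computed by birthday arithmetic from the date of
   birth;
3. **continuous enrollment** with both medical and pharmacy coverage over
   the 6-calendar-month baseline and the 365-day follow-up
   `[index, index + 364]`;
4. **no clinical-trial enrollment**, recorded as a boolean input flag
   (claims data do not identify trial participation in any standard way,
   so detection is left to the data preparer).

The rules are applied in this order and a selection (attrition) table
records the count remaining after each step. Eligibility is a pure
function of one patient's own rows; tests verify order invariance and
independence across patients.

Two places where the plain-language definitions hide ambiguity were
resolved as follows and made configurable:

- **"6-month baseline"** means six *calendar* months back from the index
  date with day-of-month clamping (2010-03-10 → 2009-09-10; month-end
  dates clamp to the shorter month), not a fixed 180 or 183 days. The
  `baseline_months` parameter of `study_windows()` controls it.
- **"Continuous"** enrollment allows zero uncovered days by default.
  Claims studies often tolerate 30- or 45-day gaps, so
  `allowable_gap` (total uncovered days in the combined
  baseline-plus-follow-up window) is exposed; the default is strict 0.

Follow-up for every outcome is the fixed 365-day window. The recorded
`followup_end_actual` additionally censors at disenrollment, death or the
study end; death truncates observation but does not remove the patient.
Whether the index claim occurs in any particular setting is deliberately
not restricted.

# Episode construction

VOC claims are those carrying 282.42, 282.62, 282.64 or 282.69 in any
diagnosis position — a strict subset of the SCD identification set; 282.60
(unspecified sickle cell crisis status) identifies SCD but not VOC.

One clinical crisis generates several claim lines: an ER visit, an
admission spanning days, professional fees, all dated within a few days.
The grouper sorts one patient's VOC claims by
(`service_start`, `service_end`, `claim_id`) — the id as a deterministic
tie-break — and merges a claim into the running episode iff its start is
at most `gap_days` after the episode's running end (the maximum service
end seen so far), extending the end as it goes. Three decisions deserve
note:

- **Gap semantics.** "Within a 3-day gap" is read as *end-to-start*
  separation of at most 3 days: single-day claims on day 1 and day 4
  merge, day 1 and day 5 do not. A start-to-start reading exists in the
  literature; `gap_days` is a parameter, and the reading is stated here
  rather than asserted as the only one.
- **Duration** is inclusive: `end − start + 1`, so a single-day episode
  has duration 1.
- **Equivalence.** The sequential sweep equals connected components of
  the "interval separation ≤ gap" graph. The test suite checks this
  against an independent union-find oracle on 1000 random claim sets, and
  checks the monotonicity property (episode count non-increasing in the
  gap, collapsing to a single episode once the gap exceeds the span).

Each episode's **setting** is the highest-priority setting among its
member claims under inpatient > ER > outpatient > office > other.
Outpatient covers outpatient hospital, ambulatory surgery center and
long-term-care/nursing facilities; office covers clinic-type places of
service; "other" absorbs every remaining facility type (lab, hospice, and
anything unmapped is a hard error rather than a silent "other").

Episode membership for the frequency strata (0, 1, 2, 3+) is by *episode
start date* inside the follow-up window; episodes may span the window
boundary.

# Comorbidity scoring

The Charlson Comorbidity Index uses the Deyo ICD-9-CM adaptation with the
original weights (1, 2, 3, 6). The mapping ships as an editable YAML file
(`inst/extdata/cci_map.yaml`) rather than code: no single mapping is
canonical, and code lists are configuration. Each condition counts once
regardless of claim or diagnosis multiplicity, and the standard hierarchy
applies (complicated diabetes supersedes diabetes; moderate/severe liver
disease supersedes mild; metastatic tumor supersedes any malignancy).
SCD-related codes themselves are not excluded from scoring; with the
shipped map they do not match any Charlson category, but a custom map
could change that, which is why the map is data.

Baseline condition flags (asthma, fever, infectious disease, …) likewise
come from a YAML stem list; the published condition names do not pin down
code sets, so the shipped stems are documented defaults.

A subtlety of baseline VOC burden: since the index date is the *first*
SCD claim inside the identification period, a baseline VOC claim can only
exist dated before that period starts (for patients indexed early). The
eligibility fixture contains exactly this configuration to keep the
baseline episode logic honest.

# Cost analytics

- **CPI adjustment.** Paid amounts are stored in service-year dollars and
  restated to 2013 dollars via the medical-care CPI multipliers in
  `inst/extdata/cpi_medical.yaml`. The shipped factors are documented
  placeholder approximations with a slot for the official series;
  adjustment is linear and the reference year is the identity.
- **SCD-relatedness.** A medical claim is SCD-related iff it carries an
  SCD diagnosis in any position or a transfusion procedure flag; a
  pharmacy claim iff its drug class is one of the SCD-management classes
  (opioids, NSAIDs, hydroxyurea, antibiotics, acetaminophen, folic acid —
  configurable in `scd_rules()`).
- **Visits.** A "visit" is one claim line per facility type per service
  day, deduplicated; inpatient utilization counts distinct admissions
  (overlapping or abutting inpatient spans merged) with length of stay as
  summed inclusive days.
- **Costing population.** Utilization percentages are computed over the
  whole cohort; dollar summaries over fee-for-service members only
  (managed-care plans do not record payment amounts in this data model),
  with zero-cost members contributing zeros to means and medians.
- **The total row** sums inpatient, the four outpatient categories,
  long-term care and pharmacy per patient before summarization, matching
  the conventional "inpatient + outpatient + LTC + pharmacy" total; lab,
  hospice and ambulatory surgery center are reported as rows but excluded
  from the total.
- **Per-episode costs** include *all* medical claims (any setting, any
  diagnosis) whose service start falls inside the episode window, plus
  SCD-class pharmacy fills in the window — the episode captures the full
  cost of care during a crisis, not only VOC-coded lines. Because merged
  episode windows are disjoint by construction, each claim is attributed
  to at most one episode; this partition property is tested. Per-episode
  totals and annual totals deliberately share claims and are not expected
  to reconcile.
- **The cost frequency distribution** drops zero-total patients (a zero
  may mean cost was not captured) and bins the rest on a configurable
  grid; the annual summaries keep zeros.

# The synthetic data generator

Real Medicaid extract data cannot be redistributed, so the package ships
a generator whose output has the statistical *structure* the analysis
assumes, with a ground-truth episode table for verification.

What it emulates, with defaults chosen once to mirror the published
cohort where stated and to be field-plausible where not:

- demographic marginals: 67.3% female; race, region and age-band
  probabilities matching the published Table-1 distribution; 49.8%
  fee-for-service;
- episode counts: negative binomial (mean 2.0, dispersion size 0.3 — the
  mean yields roughly half the cohort with no episode and a heavy 3+
  tail, matching the published strata ordering; no dispersion is
  published, so the size parameter is a stand-in);
- claim costs: lognormal per facility type with location parameters
  ordered so mean per-episode costs rank inpatient > ER > outpatient >
  office, the published ordering; magnitudes are plausible but not
  calibrated to the published dollar values;
- background (non-VOC) claims at 8 per patient-year with a diagnosis pool
  weighted so chronic Charlson conditions are rare — the resulting CCI-0
  share (~65%) mirrors a young, largely comorbidity-free population;
- enrollment churn (12% disenrollment before follow-up completes, rare
  missing-pharmacy-coverage baselines), clinical-trial flags, under-18
  patients, and post-follow-up deaths, so every eligibility rule has
  real attrition.

The construction guarantees, for any seed: every generated episode is
realized as VOC-coded claims with intra-episode start gaps ≤ 3 days;
inter-episode gaps strictly exceed 3 days (placement by slack allocation,
with a fallback to single-day episodes for extreme negative-binomial
draws, capped at the 73 episodes that fit a 365-day window); member
claims' facility types all map to the episode's designated setting (an
inpatient episode may add an admission-day ER claim, which the hierarchy
absorbs); background claims never carry VOC codes; and no SCD-coded claim
precedes the designated index claim inside the identification period.
Consequently the grouper recovers the ground truth *exactly*, and the
recovery test is a genuine end-to-end check of claim realization, not a
tautology — any off-by-one in gap arithmetic, sorting, or window
construction breaks it.

What it does **not** emulate: temporally clustered crises (inter-episode
spacing is uniform given the gap constraint, chosen to keep ground truth
identifiable), seasonal effects, state geography, managed-care data
completeness, coding error, home-managed crises invisible to claims, or
baseline VOC episodes (only the hand-built fixture exercises those).
Passing tests therefore demonstrate correctness of the *definitions and
arithmetic* on structurally realistic data, not calibration to any real
population's magnitudes.

# Numerical and testing choices

- Dates are integer days (`data.table::IDate`); all windows are closed
  intervals `[start, end]`. Determinism needs no floating-point care.
- The generator fixes the RNG kind (Mersenne-Twister / Inversion /
  Rejection) so a seed reproduces byte-identical output across platforms
  and R versions.
- Diagnosis strings are stored undotted (`"28262"`) in MAX style,
  normalized on load, with dotted accessors — eliminating dot/no-dot
  mismatch as a bug class. Prefix matching for condition maps operates on
  the undotted form.
- Tie-breaks: simultaneous claims sort by claim id; stable and
  documented.
- Degenerate inputs — empty tables, empty cohorts, patients with no
  claims, zero-episode strata — return empty or zero-valued structures
  rather than errors, and are unit-tested.
- Problem sizes: property tests run on 150–1000 randomized small claim
  sets; study-scale checks use 5000 simulated patients (a few seconds to
  generate and analyze), which makes the negative-binomial mean
  measurable to within a few percent and the stratified cost ordering
  stable.

# Known limitations

- The CPI factors are placeholders; users analyzing real data must
  supply the official series.
- The Deyo mapping and condition stems are defaults; the published
  analysis did not disclose its exact code lists, so exact concordance
  with it cannot be claimed.
- Multi-line institutional claims are treated as independent claim lines;
  transfer de-duplication (same-day inpatient + ER "visits") is not
  attempted beyond the admission-span merge.
- The per-episode and annual cost summaries intentionally share claims;
  no reconciliation between them is defined.
- Managed-care members contribute utilization but no costs, exactly as
  the data model dictates; no imputation is attempted.
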
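#' Configuration for the synthetic Medicaid-style claims generator
#'
#' Defaults encode the study conditions the pipeline is meant to exercise:
#' demographic marginals matching the published cohort (67.3% female, 74%
#' Black, mostly 18-30, ~50% fee-for-service), an overdispersed negative
#' binomial for the annual VOC episode count (claims episode counts have a
#' long right tail), right-skewed lognormal claim costs with
#' setting-dependent magnitudes ordered inpatient > ER > outpatient >
#' office, a 3-day within-episode gap bound, and enrollment churn. All
#' distributional parameters are stand-ins chosen for qualitative realism,
#' not calibrated to restricted data.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer seed fixing the entire output stream.
#' @param prop_female probability of female sex.
#' @param race_probs,region_probs,plan_probs,age_band_probs named
#'   probability vectors (must sum to 1).
#' @param episode_rate_mean,episode_dispersion negative-binomial mean and
#'   size for the number of VOC episodes in the 365-day follow-up.
#' @param claims_per_episode_mean mean claims per episode (>= 1).
#' @param gap_within_episode_max_days maximum day gap between consecutive
#'   claims inside one episode; inter-episode gaps always exceed it.
#' @param setting_probs probability of each care setting per episode.
#' @param cost_lognormal_params named list per facility type:
#'   `c(meanlog, sdlog)` of the 2013-dollar claim cost.
#' @param background_claim_rate Poisson rate (per patient-year) of non-VOC
#'   medical claims.
#' @param pharmacy_fill_rate Poisson rate (per patient-year) of pharmacy
#'   fills.
#' @param enrollment_dropout_prob probability of disenrollment before the
#'   12-month follow-up completes.
#' @param pharmacy_gap_prob probability the baseline span lacks pharmacy
#'   coverage.
#' @param clinical_trial_prob,death_prob,minor_prob probabilities of a
#'   clinical-trial flag, a recorded death after follow-up, and an under-18
#'   patient.
#' @param cpi_factors service-year -> 2013-dollar multipliers; generated
#'   paid amounts are stored in service-year dollars.
#' @param windows a [study_windows()] object (index dates are drawn in its
#'   identification period).
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_patients = 1000L,
                         seed = 1L,
                         prop_female = 0.673,
                         race_probs = c(white = 0.063, black = 0.740,
                                        hispanic = 0.101, other = 0.029,
                                        unknown = 0.067),
                         region_probs = c(northeast = 0.446, south = 0.266,
                                          west = 0.189, north_central = 0.099),
                         plan_probs = c(FFS = 0.498, managed_care = 0.502),
                         age_band_probs = c(`18-30` = 0.519, `31-45` = 0.296,
                                            `46-64` = 0.179, `65+` = 0.006),
                         episode_rate_mean = 2.0,
                         episode_dispersion = 0.3,
                         claims_per_episode_mean = 2.0,
                         gap_within_episode_max_days = 3L,
                         setting_probs = c(inpatient = 0.378, er = 0.362,
                                           outpatient = 0.182, office = 0.058,
                                           other = 0.020),
                         cost_lognormal_params = list(
                           inpatient = c(meanlog = log(9000), sdlog = 0.9),
                           outpatient_er = c(meanlog = log(700), sdlog = 0.8),
                           outpatient_hospital = c(meanlog = log(350),
                                                   sdlog = 0.8),
                           outpatient_office = c(meanlog = log(120),
                                                 sdlog = 0.6),
                           outpatient_other = c(meanlog = log(150),
                                                sdlog = 0.8),
                           ambulatory_surgery_center = c(meanlog = log(300),
                                                         sdlog = 0.7),
                           lab = c(meanlog = log(30), sdlog = 0.6),
                           hospice = c(meanlog = log(200), sdlog = 0.7),
                           long_term_care = c(meanlog = log(400), sdlog = 0.7),
                           pharmacy = c(meanlog = log(60), sdlog = 1.0)),
                         background_claim_rate = 8,
                         pharmacy_fill_rate = 6,
                         enrollment_dropout_prob = 0.12,
                         pharmacy_gap_prob = 0.02,
                         clinical_trial_prob = 0.01,
                         death_prob = 0.01,
                         minor_prob = 0.03,
                         cpi_factors = load_cpi_table(),
                         windows = study_windows()) {
  cfg <- as.list(environment())
  for (nm in c("race_probs", "region_probs", "plan_probs", "age_band_probs",
               "setting_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(nm, " must be a non-negative probability vector summing to 1")
    }
  }
  stopifnot(n_patients >= 0, prop_female >= 0, prop_female <= 1,
            episode_rate_mean >= 0, episode_dispersion > 0,
            claims_per_episode_mean >= 1,
            gap_within_episode_max_days >= 0,
            background_claim_rate >= 0, pharmacy_fill_rate >= 0,
            enrollment_dropout_prob >= 0, enrollment_dropout_prob <= 1)
  stopifnot(setequal(names(cfg$cost_lognormal_params), facility_types()))
  stopifnot(identical(sort(names(cfg$setting_probs)), sort(care_settings())))
  class(cfg) <- "synth_config"
  cfg
}

## facility pools realizing each care setting (claims drawn from a pool
## keep the episode's hierarchy-assigned setting equal to the true one)
.setting_pools <- list(
  inpatient = c(inpatient = 1),
  er = c(outpatient_er = 1),
  outpatient = c(outpatient_hospital = 0.8, ambulatory_surgery_center = 0.1,
                 long_term_care = 0.1),
  office = c(outpatient_office = 1),
  other = c(outpatient_other = 0.8, lab = 0.2)
)

## non-SCD diagnosis pool for background claims, weighted so routine
## primary-care codes dominate and chronic Charlson conditions stay rare,
## mirroring a young, mostly comorbidity-free adult population; the rare
## codes keep every CCI weight class and comorbidity flag exercised
.background_dx_weights <- c(
  ## common acute / routine codes
  "4019" = 1, "7806" = 1, "486" = 1, "78959" = 1, "V700" = 1, "4659" = 1,
  "27500" = 0.5, "73342" = 0.5, "33829" = 0.5, "5640" = 1, "0389" = 1,
  "5173" = 0.3, "78060" = 1, "2859" = 1, "78900" = 1, "5990" = 1,
  "34590" = 0.5,
  ## Charlson-triggering chronic codes, deliberately rare
  "25000" = 0.20, "25040" = 0.08, "49390" = 0.60, "1628" = 0.05,
  "1970" = 0.02, "20280" = 0.05, "042" = 0.05, "4280" = 0.12,
  "5853" = 0.10, "496" = 0.20, "71000" = 0.08, "53140" = 0.10,
  "41001" = 0.08)
.background_dx <- names(.background_dx_weights)

## SCD codes that are not VOC codes (usable anywhere post-index)
.scd_non_voc <- function() setdiff(scd_codes(), voc_codes())

#' Generate a synthetic claims dataset with recoverable ground truth
#'
#' Produces a full [claims_bundle()] plus a ground-truth episode table. By
#' construction every generated VOC episode is realized as one or more
#' VOC-coded claims whose intra-episode gaps are at most
#' `gap_within_episode_max_days` while inter-episode gaps always exceed it,
#' so [build_episodes()] with the matching gap recovers the true episode
#' count, windows and settings exactly; background claims never carry VOC
#' codes and never precede the index claim with an SCD code, so the index
#' date is recoverable too. Output is deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @return list with `bundle` (a `claims_bundle`), `ground_truth`
#'   (`patient_id`, `episode_index`, `start`, `end`, `n_claims`,
#'   `setting`), and `config`.
#' @export
generate_claims <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  n <- as.integer(config$n_patients)
  w <- config$windows
  empty_gt <- data.table(patient_id = character(), episode_index = integer(),
                         start = as.IDate(integer()),
                         end = as.IDate(integer()),
                         n_claims = integer(), setting = character())
  if (n == 0L) {
    b <- claims_bundle(
      data.table(patient_id = character(), birth_date = as.IDate(integer()),
                 sex = character(), race = character(), region = character(),
                 plan_type = character(), death_date = as.IDate(integer()),
                 clinical_trial_flag = logical()),
      data.table(claim_id = character(), patient_id = character(),
                 service_start = as.IDate(integer()),
                 service_end = as.IDate(integer()), dx_codes = character(),
                 pos_code = character(), is_transfusion = logical(),
                 paid_amount = numeric(), service_year = integer()),
      data.table(claim_id = character(), patient_id = character(),
                 fill_date = as.IDate(integer()), drug_class = character(),
                 paid_amount = numeric(), service_year = integer()),
      data.table(patient_id = character(), span_start = as.IDate(integer()),
                 span_end = as.IDate(integer()), medical_coverage = logical(),
                 pharmacy_coverage = logical()))
    return(list(bundle = b, ground_truth = empty_gt, config = config))
  }

  pid <- sprintf("P%05d", seq_len(n))

  ## ---- demographics ----
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(config$prop_female, 1 - config$prop_female))
  race <- sample(names(config$race_probs), n, TRUE, config$race_probs)
  region <- sample(names(config$region_probs), n, TRUE, config$region_probs)
  plan <- sample(names(config$plan_probs), n, TRUE, config$plan_probs)
  band <- sample(names(config$age_band_probs), n, TRUE,
                 config$age_band_probs)
  age <- integer(n)
  age[band == "18-30"] <- sample(18:30, sum(band == "18-30"), TRUE)
  age[band == "31-45"] <- sample(31:45, sum(band == "31-45"), TRUE)
  age[band == "46-64"] <- sample(46:64, sum(band == "46-64"), TRUE)
  age[band == "65+"] <- sample(65:75, sum(band == "65+"), TRUE)
  minor <- runif(n) < config$minor_prob
  age[minor] <- sample(2:16, sum(minor), TRUE)

  index <- as.IDate(sample(as.integer(w$id_period_start):
                             as.integer(w$id_period_end), n, TRUE))
  ## birth date placed so age in completed years at index equals `age`
  birth <- index - as.integer(round(age * 365.25)) - sample(10:300, n, TRUE)
  trial <- runif(n) < config$clinical_trial_prob
  died <- runif(n) < config$death_prob
  death <- as.IDate(rep(NA_integer_, n))
  death[died] <- index[died] + 365L + sample(30:400, sum(died), TRUE)
  patients <- data.table(patient_id = pid, birth_date = as.IDate(birth),
                         sex = sex, race = race, region = region,
                         plan_type = plan, death_date = death,
                         clinical_trial_flag = trial)

  ## ---- enrollment spans ----
  base_start <- add_months(index, -w$baseline_months) -
    sample(0:120, n, TRUE)
  dropout <- runif(n) < config$enrollment_dropout_prob
  span_end <- index + (w$followup_days - 1L) + sample(0:200, n, TRUE)
  span_end[dropout] <- index[dropout] + sample(60:300, sum(dropout), TRUE)
  pharm_gap <- !dropout & runif(n) < config$pharmacy_gap_prob
  split_span <- !pharm_gap & runif(n) < 0.25

  enr_list <- list(
    ## pharmacy-gap patients: medical-only baseline, full coverage after
    data.table(patient_id = pid[pharm_gap],
               span_start = base_start[pharm_gap],
               span_end = index[pharm_gap] - 1L,
               medical_coverage = TRUE, pharmacy_coverage = FALSE),
    data.table(patient_id = pid[pharm_gap],
               span_start = index[pharm_gap],
               span_end = span_end[pharm_gap],
               medical_coverage = TRUE, pharmacy_coverage = TRUE),
    ## split-span patients: two abutting fully-covered spans
    data.table(patient_id = pid[split_span],
               span_start = base_start[split_span],
               span_end = index[split_span] + 30L,
               medical_coverage = TRUE, pharmacy_coverage = TRUE),
    data.table(patient_id = pid[split_span],
               span_start = index[split_span] + 31L,
               span_end = span_end[split_span],
               medical_coverage = TRUE, pharmacy_coverage = TRUE),
    ## everyone else: one span
    data.table(patient_id = pid[!pharm_gap & !split_span],
               span_start = base_start[!pharm_gap & !split_span],
               span_end = span_end[!pharm_gap & !split_span],
               medical_coverage = TRUE, pharmacy_coverage = TRUE)
  )
  enrollment <- rbindlist(enr_list)

  ## ---- VOC episodes and their claims (per-patient construction) ----
  gap <- as.integer(config$gap_within_episode_max_days)
  fu_len <- as.integer(w$followup_days)           # days 0 .. fu_len-1
  max_ep <- (fu_len + gap + 1L) %/% (gap + 2L)    # all-singleton feasibility
  n_ep <- pmin(rnbinom(n, size = config$episode_dispersion,
                       mu = config$episode_rate_mean), max_ep)
  lp <- config$cost_lognormal_params
  cpi <- config$cpi_factors

  gt_acc <- vector("list", n)
  cl_acc <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_ep[i]
    if (k == 0L) next
    settings <- sample(names(config$setting_probs), k, TRUE,
                       config$setting_probs)
    ## per-episode member-claim start offsets (relative to episode start)
    ## and durations; intra-episode start gaps are in 0..gap
    offs <- vector("list", k)
    ends <- vector("list", k)
    durs <- integer(k)
    for (j in seq_len(k)) {
      if (settings[j] == "inpatient") {
        d <- 1L + min(rpois(1, 4), 13L)
        offs[[j]] <- 0L
        ends[[j]] <- d - 1L
        if (runif(1) < 0.3) {            # ER claim on admission day
          offs[[j]] <- c(0L, 0L)
          ends[[j]] <- c(d - 1L, 0L)
        }
        durs[j] <- d
      } else {
        nk <- 1L + min(rpois(1, config$claims_per_episode_mean - 1), 5L)
        steps <- if (nk > 1L) sample(0:gap, nk - 1L, TRUE) else integer()
        o <- cumsum(c(0L, steps))
        offs[[j]] <- o
        ends[[j]] <- o
        durs[j] <- max(o) + 1L
      }
    }
    required <- sum(durs) + (gap + 1L) * (k - 1L)
    if (required > fu_len) {
      ## rare heavy-tail draw: fall back to single-day single-claim episodes
      offs <- rep(list(0L), k); ends <- rep(list(0L), k)
      durs <- rep(1L, k)
      required <- sum(durs) + (gap + 1L) * (k - 1L)
    }
    slack <- fu_len - required
    extra <- {
      s <- sort(sample(0:slack, k, TRUE))
      c(s[1], diff(s))
    }
    starts <- integer(k)
    run <- 0L
    for (j in seq_len(k)) {
      starts[j] <- run + extra[j]
      run <- starts[j] + durs[j] - 1L + gap + 1L
    }
    ep_start <- index[i] + starts
    ep_end <- index[i] + starts + durs - 1L

    ## realize member claims
    cl_off <- unlist(offs)
    cl_endoff <- unlist(ends)
    ep_of_claim <- rep(seq_len(k), lengths(offs))
    cstart <- index[i] + starts[ep_of_claim] + cl_off
    cend <- index[i] + starts[ep_of_claim] + cl_endoff
    pos <- character(length(cl_off))
    for (j in seq_len(k)) {
      idx <- which(ep_of_claim == j)
      if (settings[j] == "inpatient") {
        pos[idx] <- if (length(idx) > 1L) c("inpatient", "outpatient_er")
          else "inpatient"
      } else {
        pool <- .setting_pools[[settings[j]]]
        pos[idx] <- sample(names(pool), length(idx), TRUE, pool)
      }
    }
    voc <- sample(voc_codes(), length(cl_off), TRUE,
                  prob = c(0.05, 0.75, 0.05, 0.15))
    extra_dx <- runif(length(cl_off)) < 0.3
    dx <- voc
    dx[extra_dx] <- paste0(
      sample(.background_dx, sum(extra_dx), TRUE,
             prob = .background_dx_weights),
      ";", voc[extra_dx])
    gt_acc[[i]] <- list(episode_index = seq_len(k),
                        start = as.integer(ep_start),
                        end = as.integer(ep_end),
                        n_claims = tabulate(ep_of_claim, k),
                        setting = settings)
    cl_acc[[i]] <- list(start = as.integer(cstart), end = as.integer(cend),
                        pos = pos, dx = dx,
                        transf = pos == "inpatient" & runif(length(pos)) < 0.05)
  }

  gt_n <- vapply(gt_acc, function(x) if (is.null(x)) 0L else
    length(x$episode_index), 0L)
  ground_truth <- data.table(
    patient_id = rep(pid, gt_n),
    episode_index = unlist(lapply(gt_acc, `[[`, "episode_index")),
    start = as.IDate(unlist(lapply(gt_acc, `[[`, "start"))),
    end = as.IDate(unlist(lapply(gt_acc, `[[`, "end"))),
    n_claims = unlist(lapply(gt_acc, `[[`, "n_claims")),
    setting = unlist(lapply(gt_acc, `[[`, "setting")))
  if (!nrow(ground_truth)) ground_truth <- empty_gt

  cl_n <- vapply(cl_acc, function(x) if (is.null(x)) 0L else
    length(x$start), 0L)
  voc_claims <- data.table(
    patient_id = rep(pid, cl_n),
    service_start = as.IDate(unlist(lapply(cl_acc, `[[`, "start"))),
    service_end = as.IDate(unlist(lapply(cl_acc, `[[`, "end"))),
    pos_code = unlist(lapply(cl_acc, `[[`, "pos")),
    dx_codes = unlist(lapply(cl_acc, `[[`, "dx")),
    is_transfusion = unlist(lapply(cl_acc, `[[`, "transf")))

  ## ---- index claims (first SCD-coded claim, non-VOC SCD code) ----
  index_claims <- data.table(
    patient_id = pid,
    service_start = index, service_end = index,
    pos_code = sample(c("outpatient_hospital", "outpatient_er",
                        "outpatient_office"), n, TRUE, c(0.5, 0.3, 0.2)),
    dx_codes = sample(.scd_non_voc(), n, TRUE),
    is_transfusion = FALSE)

  ## ---- background (never VOC-coded; SCD codes only post-index) ----
  exposure <- (as.integer(w$followup_days) + 183) / 365.25
  n_bg <- rpois(n, config$background_claim_rate * exposure)
  bg_pid <- rep(pid, n_bg)
  bg_index <- rep(index, n_bg)
  data_start <- as.IDate(sprintf("%d-01-01",
                                 as.integer(format(as.Date(w$id_period_start),
                                                   "%Y"))))
  off <- sample(-183:(fu_len - 1L), sum(n_bg), TRUE)
  bg_start <- bg_index + off
  bg_start[bg_start < data_start] <- data_start
  bg_fac_probs <- c(outpatient_hospital = 0.30, outpatient_office = 0.25,
                    outpatient_er = 0.12, outpatient_other = 0.12,
                    lab = 0.12, inpatient = 0.05,
                    ambulatory_surgery_center = 0.02,
                    long_term_care = 0.015, hospice = 0.005)
  bg_fac_probs <- bg_fac_probs / sum(bg_fac_probs)
  bg_pos <- sample(names(bg_fac_probs), sum(n_bg), TRUE, bg_fac_probs)
  bg_end <- bg_start
  ip_bg <- bg_pos == "inpatient"
  bg_end[ip_bg] <- bg_start[ip_bg] + sample(0:4, sum(ip_bg), TRUE)
  bg_dx <- sample(.background_dx, sum(n_bg), TRUE,
                  prob = .background_dx_weights)
  scd_tag <- off >= 0L & runif(sum(n_bg)) < 0.25
  bg_dx[scd_tag] <- paste0(bg_dx[scd_tag], ";",
                           sample(.scd_non_voc(), sum(scd_tag), TRUE))
  background <- data.table(
    patient_id = bg_pid, service_start = bg_start, service_end = bg_end,
    pos_code = bg_pos, dx_codes = bg_dx,
    is_transfusion = runif(sum(n_bg)) < 0.05)

  medical <- rbind(voc_claims, index_claims, background)
  setorder(medical, patient_id, service_start, service_end, pos_code,
           dx_codes)
  medical[, service_year := as.integer(format(as.Date(service_start), "%Y"))]
  meanlog_map <- vapply(lp, `[[`, 0, "meanlog")
  sdlog_map <- vapply(lp, `[[`, 0, "sdlog")
  cost_2013 <- rlnorm(nrow(medical), meanlog_map[medical$pos_code],
                      sdlog_map[medical$pos_code])
  medical[, paid_amount := round(cost_2013 /
                                   adjust_cost(1, service_year, cpi), 2)]
  medical[, claim_id := sprintf("M%07d", .I)]
  setcolorder(medical, .table_columns$medical)

  ## ---- pharmacy fills ----
  n_rx <- rpois(n, config$pharmacy_fill_rate * exposure)
  rx_pid <- rep(pid, n_rx)
  rx_date <- rep(index, n_rx) + sample(-183:(fu_len - 1L), sum(n_rx), TRUE)
  rx_date[rx_date < data_start] <- data_start
  rx_class <- sample(.enum_levels$drug_class, sum(n_rx), TRUE,
                     prob = c(0.18, 0.17, 0.12, 0.15, 0.12, 0.05, 0.21))
  pharmacy <- data.table(patient_id = rx_pid, fill_date = rx_date,
                         drug_class = rx_class)
  setorder(pharmacy, patient_id, fill_date, drug_class)
  pharmacy[, service_year := as.integer(format(as.Date(fill_date), "%Y"))]
  pharmacy[, paid_amount := round(
    rlnorm(.N, lp$pharmacy[["meanlog"]], lp$pharmacy[["sdlog"]]) /
      adjust_cost(1, service_year, cpi), 2)]
  pharmacy[, claim_id := sprintf("R%07d", .I)]
  setcolorder(pharmacy, .table_columns$pharmacy)

  bundle <- claims_bundle(patients, medical, pharmacy, enrollment)
  setorder(ground_truth, patient_id, episode_index)
  list(bundle = bundle, ground_truth = ground_truth[], config = config)
}
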
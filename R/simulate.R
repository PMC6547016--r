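#' Synthetic ward-cohort configuration
#'
#' Defaults emulate the published cohort characteristics of an oxygen-using
#' ward population: roughly 38% of admissions receive oxygen, vital-sign
#' marginals match the reported oxygen-cohort means/SDs (HR 84 (18), RR 18
#' (4), SBP 125 (23), temperature 36.7 (0.6), FiO2 47% (15%)), admission-level
#' adverse-event prevalence is about 4% overall (6-7% in the oxygen cohort),
#' and the per-admission event probability in the oxygen cohort steps up
#' through the planted FiO2 cut-points, so the event hazard genuinely
#' increases with inspired oxygen.
#'
#' @param n_admissions Number of admissions to generate.
#' @param oxygen_fraction Fraction of admissions receiving oxygen therapy.
#' @param admission_event_rate Target overall admission-level event rate.
#' @param obs_per_admission Mean observation sets per admission.
#' @param vital_marginals Named list of `c(mean, sd)` for `hr`, `rr`, `sbp`,
#'   `temp` and `fio2_pct` (the oxygen-cohort FiO2 marginal, percent).
#' @param planted_fio2_cuts Three ascending FiO2 fractions through which the
#'   event probability steps.
#' @param band_event_probs Four ascending probabilities, one per planted
#'   band; also the per-observation label probabilities of
#'   [generate_banded_fio2_labels()].
#' @param drift_strength Magnitude of the physiological drift (rising RR/HR
#'   and FiO2, falling SBP/SpO2) over the final 24 h before an event;
#'   1 = default drift, 0 = none.
#' @param ineligible_fraction Fraction of admissions generated ineligible
#'   (short stays discharged alive, under-16s, post-ICU ward periods) so the
#'   eligibility filters have work to do.
#' @param missing_fraction Fraction of observation sets with a missing vital
#'   (exercises the completeness filter).
#' @param seed Optional integer seed; generation is reproducible under it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_admissions = 2000,
                       oxygen_fraction = 0.38,
                       admission_event_rate = 0.04,
                       obs_per_admission = 25,
                       vital_marginals = list(hr = c(84, 18), rr = c(18, 4),
                                              sbp = c(125, 23),
                                              temp = c(36.7, 0.6),
                                              fio2_pct = c(47, 15)),
                       planted_fio2_cuts = c(0.22, 0.37, 0.53),
                       band_event_probs = c(0.005, 0.02, 0.05, 0.12),
                       drift_strength = 1,
                       ineligible_fraction = 0.05,
                       missing_fraction = 0.01,
                       seed = NULL) {
  if (n_admissions < 1) stop_input("n_admissions must be >= 1")
  if (obs_per_admission < 1) stop_input("obs_per_admission must be >= 1")
  if (any(band_event_probs < 0 | band_event_probs > 1)) {
    stop_input("band_event_probs must be probabilities")
  }
  if (is.unsorted(planted_fio2_cuts, strictly = TRUE)) {
    stop_input("planted_fio2_cuts must be strictly ascending")
  }
  structure(as.list(environment()), class = "sim_config")
}

sim_band_prob <- function(fio2, config) {
  config$band_event_probs[findInterval(fio2, config$planted_fio2_cuts,
                                       left.open = TRUE) + 1L]
}

#' Generate a synthetic ward cohort
#'
#' Draws admissions and their vital-sign observation sets under the
#' configured marginals. Oxygen admissions carry a target FiO2 drawn from
#' the configured marginal, delivered through a device/flow combination
#' whose [estimate_fio2()] round-trips to that target; their event
#' probability follows `band_event_probs` through the planted cut-points.
#' Event admissions exhibit drift over the final 24 h (rising respiratory
#' and heart rate and FiO2, falling blood pressure and SpO2). A small
#' configured share of admissions is generated ineligible and a share of
#' observation sets incomplete, so the filtering stages are exercised
#' end to end.
#'
#' @param config A [sim_config()].
#' @return List with validated `admissions` and `observations` tibbles.
#' @export
generate_cohort <- function(config = sim_config()) {
  with_preserved_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_admissions
  vm <- config$vital_marginals
  admission_id <- sprintf("A%06d", seq_len(n))
  patient_id <- sprintf("P%06d", sample.int(max(1, ceiling(0.85 * n)), n,
                                            replace = TRUE))
  age <- round(rtruncnorm(n, 64, 19, 16, 104))

  # ineligible slices: short stays discharged alive, minors, post-ICU wards
  n_inel <- round(config$ineligible_fraction * n)
  inel <- sample.int(n, n_inel)
  inel_kind <- sample(c("short", "minor", "post_icu"), n_inel,
                      replace = TRUE, prob = c(0.4, 0.3, 0.3))
  short_stay <- seq_len(n) %in% inel[inel_kind == "short"]
  minor <- seq_len(n) %in% inel[inel_kind == "minor"]
  post_icu <- seq_len(n) %in% inel[inel_kind == "post_icu"]
  age[minor] <- sample(1:15, sum(minor), replace = TRUE)

  on_oxygen <- runif(n) < config$oxygen_fraction
  fio2_target <- rep(NA_real_, n)
  fio2_target[on_oxygen] <- rtruncnorm(sum(on_oxygen), vm$fio2_pct[1] / 100,
                                       vm$fio2_pct[2] / 100, 0.22, 1.0)

  # admission-level event probability: banded for the oxygen cohort, and a
  # baseline for the rest chosen so the overall rate hits the configured one
  p_event <- rep(NA_real_, n)
  p_event[on_oxygen] <- sim_band_prob(fio2_target[on_oxygen], config)
  mean_pox <- if (any(on_oxygen)) mean(p_event[on_oxygen]) else 0
  frac_ox <- mean(on_oxygen)
  p_base <- (config$admission_event_rate - frac_ox * mean_pox) /
    max(1e-9, 1 - frac_ox)
  p_event[!on_oxygen] <- min(1, max(0.002, p_base))
  event <- runif(n) < p_event
  event[short_stay] <- FALSE

  stay_h <- exp(rnorm(n, log(100), 0.8))
  stay_h <- pmin(pmax(stay_h, 26), 1500)
  stay_h[short_stay] <- runif(sum(short_stay), 2, 20)

  admit_time <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
    round(runif(n, 0, 365 * 24 * 3600))
  event_frac <- runif(n, 0.3, 0.95)
  event_time <- as.POSIXct(rep(NA, n), tz = "UTC")
  event_time[event] <- admit_time[event] + round(event_frac[event] *
                                                   stay_h[event] * 3600)
  outcome <- rep("none", n)
  outcome[event] <- sample(c("death", "unplanned_icu"), sum(event),
                           replace = TRUE, prob = c(0.6, 0.4))
  discharge_time <- admit_time + round(stay_h * 3600)
  died <- outcome == "death"
  discharge_time[died] <- event_time[died]

  admissions <- tibble(admission_id = admission_id, patient_id = patient_id,
                       age_years = as.integer(age),
                       admit_time = admit_time,
                       discharge_time = discharge_time,
                       outcome = outcome, event_time = event_time,
                       planned_icu_before_ward = post_icu)

  # -- observation sets ------------------------------------------------------
  n_obs_per <- 1L + rpois(n, max(0, config$obs_per_admission - 1))
  obs_stay_h <- hours_between(discharge_time, admit_time)
  obs <- purrr::map_dfr(seq_len(n), function(i) {
    k <- n_obs_per[i]
    gaps <- rexp(k, rate = k / max(obs_stay_h[i], 1))
    t_h <- cumsum(gaps)
    t_h <- t_h[t_h < obs_stay_h[i]]
    if (length(t_h) == 0) t_h <- obs_stay_h[i] * runif(1, 0.1, 0.9)
    tibble(admission_id = admission_id[i],
           timestamp = admit_time[i] + round(t_h * 3600))
  })
  m <- nrow(obs)
  ai <- match(obs$admission_id, admission_id)

  tte <- hours_between(event_time[ai], obs$timestamp)
  drift <- ifelse(!is.na(tte) & tte >= 0 & tte <= 24,
                  config$drift_strength * (1 - tte / 24), 0)

  rr <- rtruncnorm(m, vm$rr[1], vm$rr[2], 6, 45) + 6 * drift
  hr <- rtruncnorm(m, vm$hr[1], vm$hr[2], 30, 190) + 14 * drift
  sbp <- rtruncnorm(m, vm$sbp[1], vm$sbp[2], 65, 245) - 15 * drift
  temp <- round(rtruncnorm(m, vm$temp[1], vm$temp[2], 34, 41), 1)
  spo2 <- 100 - stats::rgamma(m, shape = 2, scale = 1.5) - 4 * drift
  rr <- as.integer(round(pmin(pmax(rr, 6), 50)))
  hr <- as.integer(round(pmin(pmax(hr, 30), 200)))
  sbp <- as.integer(round(pmin(pmax(sbp, 60), 250)))
  spo2 <- as.integer(round(pmin(pmax(spo2, 70), 100)))

  avpu <- sample(avpu_levels(), m, replace = TRUE,
                 prob = c(0.97, 0.02, 0.007, 0.003))
  gcs <- rep(NA_integer_, m)
  use_gcs <- runif(m) < 0.10
  gcs[use_gcs] <- dplyr::case_when(
    avpu[use_gcs] == "A" ~ 15L,
    avpu[use_gcs] == "V" ~ as.integer(sample(9:14, sum(use_gcs), replace = TRUE)),
    avpu[use_gcs] == "P" ~ as.integer(sample(4:8, sum(use_gcs), replace = TRUE)),
    TRUE ~ 3L
  )
  avpu[use_gcs] <- NA_character_

  # oxygen delivery consistent with the admission's (drifted) target FiO2
  f <- fio2_target[ai] + 0.15 * drift + rnorm(m, 0, 0.03)
  f <- pmin(pmax(f, 0.215), 1)
  ox_obs <- on_oxygen[ai] & runif(m) > 0.10  # some sets taken while off oxygen
  device <- rep("room_air", m)
  flow <- rep(NA_real_, m)
  rx <- rep(NA_real_, m)
  kind <- runif(m)
  hi <- ox_obs & f >= 0.95
  device[hi] <- sample(c("high_flow_nasal", "niv"), sum(hi), replace = TRUE)
  fixed <- ox_obs & !hi & kind < 0.15
  device[fixed] <- "fixed_performance_mask"
  rx[fixed] <- round(pmin(pmax(f[fixed], 0.24), 0.60), 2)
  form <- ox_obs & !hi & !fixed
  mv <- rr[form] * 0.45
  fl <- round(mv * (f[form] - 0.21) / 0.79, 1)
  fl <- pmin(pmax(fl, 0.5), 15)
  flow[form] <- fl
  device[form] <- ifelse(fl <= 4, "nasal_cannula",
                         ifelse(fl <= 10, "simple_mask", "reservoir_mask"))

  observations <- tibble(admission_id = obs$admission_id,
                         timestamp = obs$timestamp,
                         hr = as.numeric(hr), rr = as.numeric(rr),
                         sbp = as.numeric(sbp), spo2 = as.numeric(spo2),
                         temp = temp, avpu = avpu, gcs = gcs,
                         device = device, o2_flow_lpm = flow,
                         prescribed_fio2 = rx)

  # knock out a vital on a small share of sets
  n_miss <- round(config$missing_fraction * m)
  if (n_miss > 0) {
    rows <- sample.int(m, n_miss)
    cols <- sample(c("temp", "sbp", "spo2", "hr"), n_miss, replace = TRUE)
    for (j in seq_len(n_miss)) observations[[cols[j]]][rows[j]] <- NA_real_
  }

  list(admissions = validate_admissions(admissions),
       observations = validate_observations(observations))
}

#' Generate banded FiO2 label data
#'
#' Draws calculated FiO2 uniformly over `[0.21, 1.0]` and labels each
#' observation by the band event probability through the planted cut-points.
#' This is the fixture for threshold derivation: with the default step
#' probabilities the tree should recover the planted cuts.
#'
#' @param n Number of observations.
#' @param config A [sim_config()] (uses `planted_fio2_cuts`,
#'   `band_event_probs` and `seed`).
#' @return Tibble with `calculated_fio2` and logical `label`.
#' @export
generate_banded_fio2_labels <- function(n, config = sim_config()) {
  with_preserved_seed(config$seed, {
    fio2 <- runif(n, 0.21, 1.0)
    p <- sim_band_prob(fio2, config)
    tibble(calculated_fio2 = fio2, label = runif(n) < p)
  })
}
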
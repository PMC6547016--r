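#' Cohort eligibility and labelling configuration
#'
#' @param min_age_years Minimum age at admission; default 16 (adult).
#' @param min_stay_hours Minimum stay for admissions discharged alive and
#'   event-free; default 24 h.
#' @param lookback_window_hours Look-back window within which an observation
#'   set counts as associated with an event; default 24 h.
#' @param window_inclusive Whether an observation exactly at the window
#'   boundary is labelled positive; default `TRUE`.
#' @param gcs_to_avpu_map GCS range to AVPU correspondence,
#'   see [default_gcs_avpu_map()].
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(min_age_years = 16, min_stay_hours = 24,
                          lookback_window_hours = 24, window_inclusive = TRUE,
                          gcs_to_avpu_map = default_gcs_avpu_map()) {
  if (lookback_window_hours <= 0) stop_input("lookback window must be > 0")
  covered <- unlist(purrr::map2(gcs_to_avpu_map$gcs_min, gcs_to_avpu_map$gcs_max, `:`))
  if (!setequal(covered, 3:15)) {
    stop_input("gcs_to_avpu_map must cover GCS 3-15 without gaps")
  }
  structure(list(min_age_years = min_age_years,
                 min_stay_hours = min_stay_hours,
                 lookback_window_hours = lookback_window_hours,
                 window_inclusive = window_inclusive,
                 gcs_to_avpu_map = gcs_to_avpu_map),
            class = "cohort_config")
}

#' Default GCS-to-AVPU correspondence
#'
#' A commonly used mapping (15 Alert; 9-14 Voice; 4-8 Pain; 3 Unresponsive).
#' Local conversion rules differ between hospitals; supply your own table
#' with the same columns to override.
#'
#' @return Tibble with columns `gcs_min`, `gcs_max`, `avpu`.
#' @export
default_gcs_avpu_map <- function() {
  tibble(gcs_min = c(15L, 9L, 4L, 3L),
         gcs_max = c(15L, 14L, 8L, 3L),
         avpu = c("A", "V", "P", "U"))
}

#' Convert GCS totals to AVPU levels
#'
#' @param gcs Integer GCS totals in 3-15 (vectorised).
#' @param map Range mapping, see [default_gcs_avpu_map()].
#' @return Character vector of AVPU levels.
#' @export
gcs_to_avpu <- function(gcs, map = default_gcs_avpu_map()) {
  gcs <- as.integer(gcs)
  if (anyNA(gcs) || any(gcs < 3 | gcs > 15)) {
    stop_domain("gcs must be an integer in [3, 15]")
  }
  idx <- purrr::map_int(gcs, function(g) {
    which(map$gcs_min <= g & g <= map$gcs_max)[1]
  })
  map$avpu[idx]
}

is_complete_obs <- function(obs, device_table = default_device_table()) {
  behaviour <- device_table$behaviour[match(obs$device, device_table$device)]
  vitals_ok <- !is.na(obs$hr) & !is.na(obs$rr) & !is.na(obs$sbp) &
    !is.na(obs$spo2) & !is.na(obs$temp)
  conscious_ok <- !is.na(obs$avpu) | !is.na(obs$gcs)
  gas_ok <- !is.na(obs$device) &
    (is.na(behaviour) |
       behaviour %in% c("room_air", "saturated_max") |
       (behaviour == "formula" & !is.na(obs$o2_flow_lpm)) |
       (behaviour == "prescribed" & !is.na(obs$prescribed_fio2)))
  vitals_ok & conscious_ok & gas_ok
}

#' Keep only complete vital-sign observation sets
#'
#' A complete set records all of heart rate, respiratory rate, systolic
#' blood pressure, SpO2, temperature, a consciousness level (AVPU or GCS)
#' and the inhaled-gas information required by the device (flow for
#' variable-performance devices, prescribed FiO2 for fixed-performance
#' masks).
#'
#' @param obs Observations tibble.
#' @param device_table Device behaviour table.
#' @return Complete observations; attribute `"n_incomplete"` counts removals.
#' @export
completeness_filter <- function(obs, device_table = default_device_table()) {
  obs <- as_tibble(obs)
  keep <- is_complete_obs(obs, device_table)
  out <- obs[keep, ]
  attr(out, "n_incomplete") <- sum(!keep)
  out
}

#' Apply cohort eligibility filters
#'
#' Removes admissions below the minimum age, stays shorter than the minimum
#' that ended in a live event-free discharge, admissions with no complete
#' observation set, and all observations from ward periods that followed an
#' ICU stay. Returns a flowchart-style exclusion tally alongside the
#' retained tables.
#'
#' @param admissions,observations Validated tibbles.
#' @param config A [cohort_config()].
#' @param device_table Device behaviour table (for completeness).
#' @return List with `admissions`, `observations` (complete, eligible),
#'   `exclusions` (tibble of `reason`, `n` at admission level),
#'   `n_incomplete_observations`, and `orphan_observations` (rows whose
#'   admission id matches no admission).
#' @export
filter_eligible <- function(admissions, observations,
                            config = cohort_config(),
                            device_table = default_device_table()) {
  admissions <- as_tibble(admissions)
  observations <- as_tibble(observations)
  n0 <- nrow(admissions)

  orphans <- observations[!observations$admission_id %in% admissions$admission_id, ]
  observations <- observations[observations$admission_id %in% admissions$admission_id, ]

  excl <- list()
  keep <- rep(TRUE, nrow(admissions))

  under_age <- admissions$age_years < config$min_age_years
  excl$under_age <- sum(keep & under_age)
  keep <- keep & !under_age

  stay_h <- hours_between(admissions$discharge_time, admissions$admit_time)
  short_alive <- stay_h < config$min_stay_hours & admissions$outcome == "none"
  excl$short_stay_discharged_alive <- sum(keep & short_alive)
  keep <- keep & !short_alive

  post_icu <- admissions$planned_icu_before_ward
  excl$ward_period_after_icu <- sum(keep & post_icu)
  keep <- keep & !post_icu

  complete <- completeness_filter(observations, device_table)
  n_incomplete <- attr(complete, "n_incomplete")
  has_complete <- admissions$admission_id %in% complete$admission_id
  excl$no_complete_observation_set <- sum(keep & !has_complete)
  keep <- keep & has_complete

  adm_out <- admissions[keep, ]
  obs_out <- complete[complete$admission_id %in% adm_out$admission_id, ]
  attr(obs_out, "n_incomplete") <- NULL

  exclusions <- tibble(reason = names(excl), n = unlist(excl, use.names = FALSE))
  stopifnot(sum(exclusions$n) + nrow(adm_out) == n0)
  list(admissions = adm_out, observations = obs_out, exclusions = exclusions,
       n_incomplete_observations = n_incomplete,
       orphan_observations = orphans)
}

#' Label observation sets against the 24-hour composite outcome
#'
#' For each admission the event is the earlier of unplanned ICU admission or
#' in-hospital death (the admission table already carries the first event
#' and its time). Every complete observation whose time precedes the event
#' by at most the look-back window is labelled positive and annotated with
#' its time-to-event; observations after the event are dropped; everything
#' else is labelled negative.
#'
#' @param observations Eligible complete observations.
#' @param admissions Eligible admissions.
#' @param config A [cohort_config()].
#' @return Tibble of observations with `label` (logical) and
#'   `time_to_event_h` (NA for negatives) appended; attribute
#'   `"n_post_event_dropped"` counts removed post-event rows.
#' @export
tag_events <- function(observations, admissions, config = cohort_config()) {
  observations <- as_tibble(observations)
  admissions <- as_tibble(admissions)
  ev <- admissions[, c("admission_id", "outcome", "event_time")]
  out <- left_join(observations, ev, by = "admission_id")

  tte <- hours_between(out$event_time, out$timestamp)
  post_event <- !is.na(tte) & tte < 0
  n_dropped <- sum(post_event)
  out <- out[!post_event, ]
  tte <- tte[!post_event]

  w <- config$lookback_window_hours
  in_window <- if (config$window_inclusive) {
    !is.na(tte) & tte > 0 & tte <= w
  } else {
    !is.na(tte) & tte > 0 & tte < w
  }
  out$label <- in_window
  out$time_to_event_h <- ifelse(in_window, tte, NA_real_)
  out$outcome <- NULL
  out$event_time <- NULL
  attr(out, "n_post_event_dropped") <- n_dropped
  out
}
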
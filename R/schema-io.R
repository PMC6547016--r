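#' Oxygen-delivery device categories
#'
#' The device enumeration recognised throughout the package. Behaviour per
#' device (dilution formula, prescribed value, saturated maximum) is set by
#' the device table, see [default_device_table()].
#'
#' @return Character vector of device codes.
#' @export
device_levels <- function() {
  c("room_air", "nasal_cannula", "simple_mask", "reservoir_mask",
    "fixed_performance_mask", "high_flow_nasal", "niv")
}

avpu_levels <- function() c("A", "V", "P", "U")

obs_canonical_cols <- function() {
  c("admission_id", "timestamp", "hr", "rr", "sbp", "spo2", "temp",
    "avpu", "gcs", "device", "o2_flow_lpm", "prescribed_fio2")
}

adm_canonical_cols <- function() {
  c("admission_id", "patient_id", "age_years", "admit_time", "discharge_time",
    "outcome", "event_time", "planned_icu_before_ward")
}

#' Default column mapping for delimited-text input
#'
#' Maps canonical field names to the column headers expected in CSV files.
#' Override individual entries (or supply a YAML file via
#' [read_schema_config()]) when your export uses different headers.
#'
#' @return Named list with `observations` and `admissions` character vectors
#'   (canonical name -> file column name).
#' @export
default_schema <- function() {
  list(
    observations = stats::setNames(obs_canonical_cols(), obs_canonical_cols()),
    admissions   = stats::setNames(adm_canonical_cols(), adm_canonical_cols())
  )
}

#' Read a column-mapping / configuration file
#'
#' Reads a YAML configuration holding column mappings and optional parameter
#' blocks (device table, score chart, FiO2 bands). Entries not present fall
#' back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list as stored in the file.
#' @export
read_schema_config <- function(path) {
  if (!file.exists(path)) stop_input(paste0("config file not found: ", path))
  yaml::read_yaml(path)
}

# ---- validation ------------------------------------------------------------

new_diagnostic <- function(row, field, message, severity = "reject") {
  tibble(row = as.integer(row), field = field, message = message,
         severity = severity)
}

#' Validate a table of vital-sign observation sets
#'
#' Checks every row against the domain invariants: physiological values in
#' range, known device codes, oxygen inputs consistent with the device, and
#' consciousness recorded as AVPU and/or GCS. Missing vitals are *not*
#' violations (incomplete sets are handled by [completeness_filter()]);
#' out-of-range or contradictory values are.
#'
#' @param obs Data frame of observations in canonical columns.
#' @param permissive If `FALSE` (default) any rejected row raises an error
#'   listing the row-level diagnostics; if `TRUE` rejected rows are dropped
#'   and the diagnostics are attached as the `"diagnostics"` attribute.
#' @return A validated tibble; attribute `"diagnostics"` holds a tibble with
#'   columns `row`, `field`, `message`, `severity` (`"reject"` rows were
#'   dropped under `permissive = TRUE`; `"flag"` rows are kept).
#' @export
validate_observations <- function(obs, permissive = FALSE) {
  obs <- as_tibble(obs)
  missing_cols <- setdiff(setdiff(obs_canonical_cols(), c("avpu", "gcs",
                                                          "o2_flow_lpm",
                                                          "prescribed_fio2")),
                          names(obs))
  if (length(missing_cols) > 0) {
    stop_input(paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "newsfio2_schema_error")
  }
  if (!any(c("avpu", "gcs") %in% names(obs))) {
    stop_input("need at least one consciousness column (avpu or gcs)",
               class = "newsfio2_schema_error")
  }
  for (col in c("avpu", "gcs", "o2_flow_lpm", "prescribed_fio2")) {
    if (!col %in% names(obs)) obs[[col]] <- NA
  }
  obs <- obs[, obs_canonical_cols()]
  obs$gcs <- suppressWarnings(as.integer(obs$gcs))
  for (col in c("hr", "rr", "sbp", "spo2", "temp", "o2_flow_lpm",
                "prescribed_fio2")) {
    obs[[col]] <- suppressWarnings(as.numeric(obs[[col]]))
  }

  diags <- list()
  bad <- function(mask, field, msg) {
    mask[is.na(mask)] <- FALSE
    if (any(mask)) diags[[length(diags) + 1]] <<- new_diagnostic(which(mask), field, msg)
  }

  ts <- parse_naive_datetime(obs$timestamp)
  bad(is.na(ts) & !is.na(obs$timestamp), "timestamp", "unparseable datetime")
  bad(is.na(obs$timestamp), "timestamp", "missing timestamp")
  obs$timestamp <- ts
  bad(is.na(obs$admission_id) | obs$admission_id == "", "admission_id",
      "missing admission id")
  bad(obs$spo2 < 0 | obs$spo2 > 100, "spo2", "spo2 outside [0, 100]")
  bad(obs$rr <= 0, "rr", "respiratory rate must be > 0")
  bad(obs$hr <= 0, "hr", "heart rate must be > 0")
  bad(obs$sbp <= 0, "sbp", "systolic blood pressure must be > 0")
  bad(!is.na(obs$avpu) & !obs$avpu %in% avpu_levels(), "avpu",
      "avpu must be one of A, V, P, U")
  bad(!is.na(obs$gcs) & (obs$gcs < 3 | obs$gcs > 15), "gcs",
      "gcs must be an integer in [3, 15]")
  bad(!is.na(obs$device) & !obs$device %in% device_levels(), "device",
      paste0("unknown device (expected one of ",
             paste(device_levels(), collapse = ", "), ")"))
  bad(obs$o2_flow_lpm < 0, "o2_flow_lpm", "oxygen flow must be >= 0")
  bad(!is.na(obs$device) & obs$device == "room_air" &
        !is.na(obs$o2_flow_lpm) & obs$o2_flow_lpm > 0,
      "o2_flow_lpm", "room air with positive oxygen flow")
  bad(obs$prescribed_fio2 < 0.21 | obs$prescribed_fio2 > 1,
      "prescribed_fio2", "prescribed FiO2 outside [0.21, 1.0]")

  diags <- if (length(diags) > 0) bind_rows(diags) else new_diagnostic(integer(), character(), character())[0, ]

  # duplicate-timestamp sets within an admission are kept but flagged
  dup <- duplicated(obs[, c("admission_id", "timestamp")]) |
    duplicated(obs[, c("admission_id", "timestamp")], fromLast = TRUE)
  dup[is.na(obs$timestamp)] <- FALSE
  if (any(dup)) {
    diags <- bind_rows(diags, new_diagnostic(
      which(dup), "timestamp", "duplicate timestamp within admission",
      severity = "flag"))
  }

  reject_rows <- sort(unique(diags$row[diags$severity == "reject"]))
  if (length(reject_rows) > 0 && !permissive) {
    eg <- diags[diags$severity == "reject", ][1, ]
    stop_input(paste0(length(reject_rows), " row(s) violate observation ",
                      "invariants (e.g. row ", eg$row, ": ", eg$message,
                      "); rerun with permissive = TRUE to drop them"),
               class = "newsfio2_validation_error")
  }
  if (length(reject_rows) > 0) {
    obs <- obs[-reject_rows, ]
  }
  attr(obs, "diagnostics") <- diags
  obs
}

#' Validate a table of hospital admissions
#'
#' @inheritParams validate_observations
#' @param adm Data frame of admissions in canonical columns.
#' @return Validated tibble with a `"diagnostics"` attribute as in
#'   [validate_observations()].
#' @export
validate_admissions <- function(adm, permissive = FALSE) {
  adm <- as_tibble(adm)
  missing_cols <- setdiff(setdiff(adm_canonical_cols(),
                                  c("event_time", "planned_icu_before_ward")),
                          names(adm))
  if (length(missing_cols) > 0) {
    stop_input(paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "newsfio2_schema_error")
  }
  if (!"event_time" %in% names(adm)) adm$event_time <- NA
  if (!"planned_icu_before_ward" %in% names(adm)) adm$planned_icu_before_ward <- FALSE
  adm <- adm[, adm_canonical_cols()]
  adm$age_years <- suppressWarnings(as.integer(adm$age_years))
  adm$admit_time <- parse_naive_datetime(adm$admit_time)
  adm$discharge_time <- parse_naive_datetime(adm$discharge_time)
  adm$event_time <- parse_naive_datetime(adm$event_time)
  adm$planned_icu_before_ward <- as.logical(adm$planned_icu_before_ward)
  adm$planned_icu_before_ward[is.na(adm$planned_icu_before_ward)] <- FALSE

  diags <- list()
  bad <- function(mask, field, msg) {
    mask[is.na(mask)] <- FALSE
    if (any(mask)) diags[[length(diags) + 1]] <<- new_diagnostic(which(mask), field, msg)
  }
  bad(is.na(adm$admission_id) | adm$admission_id == "", "admission_id",
      "missing admission id")
  bad(is.na(adm$age_years) | adm$age_years < 0, "age_years",
      "age must be a non-negative integer")
  bad(is.na(adm$admit_time), "admit_time", "unparseable admit time")
  bad(is.na(adm$discharge_time), "discharge_time", "unparseable discharge time")
  bad(adm$discharge_time <= adm$admit_time, "discharge_time",
      "discharge must be after admission")
  bad(!adm$outcome %in% c("none", "death", "unplanned_icu"), "outcome",
      "outcome must be none, death or unplanned_icu")
  bad(adm$outcome != "none" & is.na(adm$event_time), "event_time",
      "event outcome requires an event time")
  bad(adm$outcome == "none" & !is.na(adm$event_time), "event_time",
      "event time given for outcome 'none'")
  bad(!is.na(adm$event_time) &
        (adm$event_time < adm$admit_time | adm$event_time > adm$discharge_time),
      "event_time", "event time outside the stay interval")

  diags <- if (length(diags) > 0) bind_rows(diags) else new_diagnostic(integer(), character(), character())[0, ]
  reject_rows <- sort(unique(diags$row[diags$severity == "reject"]))
  if (length(reject_rows) > 0 && !permissive) {
    eg <- diags[1, ]
    stop_input(paste0(length(reject_rows), " admission row(s) violate ",
                      "invariants (e.g. row ", eg$row, ": ", eg$message, ")"),
               class = "newsfio2_validation_error")
  }
  if (length(reject_rows) > 0) adm <- adm[-reject_rows, ]
  attr(adm, "diagnostics") <- diags
  adm
}

# ---- readers / writers -----------------------------------------------------

apply_mapping <- function(df, mapping, what) {
  missing <- setdiff(unname(mapping), names(df))
  if (length(missing) > 0) {
    stop_input(paste0(what, " file is missing mapped column(s): ",
                      paste(missing, collapse = ", ")),
               class = "newsfio2_schema_error")
  }
  out <- df[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out
}

#' Read vital-sign observation sets from CSV
#'
#' @param path CSV file with a header row.
#' @param schema Column mapping (canonical name -> file column), as the
#'   `observations` entry of [default_schema()] or a config file.
#' @param permissive Passed to [validate_observations()].
#' @return Validated observations tibble with a `"diagnostics"` attribute.
#' @export
read_observations <- function(path, schema = default_schema()$observations,
                              permissive = FALSE) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  schema <- unlist(schema)
  optional <- c("avpu", "gcs", "o2_flow_lpm", "prescribed_fio2")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  schema <- schema[!(names(schema) %in% optional & !schema %in% names(raw))]
  validate_observations(apply_mapping(raw, schema, "observations"), permissive)
}

#' Read admissions from CSV
#'
#' @inheritParams read_observations
#' @param schema Column mapping for the admissions table.
#' @return Validated admissions tibble.
#' @export
read_admissions <- function(path, schema = default_schema()$admissions,
                            permissive = FALSE) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  schema <- unlist(schema)
  optional <- c("event_time", "planned_icu_before_ward")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  schema <- schema[!(names(schema) %in% optional & !schema %in% names(raw))]
  validate_admissions(apply_mapping(raw, schema, "admissions"), permissive)
}

#' Write observations / admissions to CSV
#'
#' Columns are written in canonical order and datetimes as timezone-naive
#' ISO-8601 (`YYYY-MM-DDTHH:MM:SS`), so `read_*` after `write_*` restores an
#' equal table.
#'
#' @param obs,adm Validated tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  out <- as_tibble(obs)[, intersect(obs_canonical_cols(), names(obs))]
  out$timestamp <- format_naive_datetime(out$timestamp)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
write_admissions <- function(adm, path) {
  out <- as_tibble(adm)[, intersect(adm_canonical_cols(), names(adm))]
  out$admit_time <- format_naive_datetime(out$admit_time)
  out$discharge_time <- format_naive_datetime(out$discharge_time)
  out$event_time <- format_naive_datetime(out$event_time)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
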
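#' Percentage as reported in cohort tables
#'
#' Share of a count in a total, in percent, rounded to the reporting
#' precision used throughout the package's summaries (one decimal place by
#' default). The single place where fractions become printed percentages.
#'
#' @param n Numerator count(s).
#' @param total Denominator count(s).
#' @param digits Decimal places; default 1.
#' @return Numeric percentage(s).
#' @export
pct_of <- function(n, total, digits = 1) {
  if (any(total <= 0)) stop_input("total must be positive")
  round(100 * n / total, digits)
}

#' Admission-level cohort summary
#'
#' Flowchart-style counts and percentages over an admissions table with its
#' observations: events among all admissions, the oxygen-requiring
#' sub-cohort (admissions with at least one supplemental-oxygen observation
#' set), and events within it.
#'
#' @param admissions Admissions tibble.
#' @param observations Observations tibble (used to identify the oxygen
#'   cohort).
#' @return One-row tibble with `n_admissions`, `n_events`, `event_pct`,
#'   `n_oxygen`, `oxygen_pct`, `n_oxygen_events`, `oxygen_event_pct`.
#' @export
cohort_summary <- function(admissions, observations) {
  admissions <- as_tibble(admissions)
  observations <- as_tibble(observations)
  ox_ids <- unique(observations$admission_id[observations$device != "room_air"])
  is_event <- admissions$outcome != "none"
  is_ox <- admissions$admission_id %in% ox_ids
  tibble(
    n_admissions = nrow(admissions),
    n_events = sum(is_event),
    event_pct = pct_of(sum(is_event), nrow(admissions)),
    n_oxygen = sum(is_ox),
    oxygen_pct = pct_of(sum(is_ox), nrow(admissions)),
    n_oxygen_events = sum(is_ox & is_event),
    oxygen_event_pct = if (any(is_ox)) pct_of(sum(is_ox & is_event), sum(is_ox)) else NA_real_
  )
}
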
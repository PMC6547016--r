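#' Default oxygen-device behaviour table
#'
#' Maps each delivery device to how its inspired oxygen fraction is obtained:
#' `"room_air"` (0.21), `"formula"` (dilution formula from flow and minute
#' volume), `"prescribed"` (taken from the prescribed FiO2, as for
#' fixed-performance Venturi masks) or `"saturated_max"` (assumed 1.0, as for
#' high-flow nasal oxygen and non-invasive ventilation). These defaults cover
#' the behaviour classes the method needs; align the table with your local
#' observation chart before applying it to real exports.
#'
#' @return Tibble with columns `device` and `behaviour`.
#' @export
default_device_table <- function() {
  tibble(
    device = device_levels(),
    behaviour = c("room_air", "formula", "formula", "formula",
                  "prescribed", "saturated_max", "saturated_max")
  )
}

#' Minute volume from respiratory rate
#'
#' Minute volume (L/min) = respiratory rate x tidal volume, with the fixed
#' default tidal volume of 0.45 L per breath used throughout the FiO2
#' calculation.
#'
#' @param rr Respiratory rate, breaths/min (> 0).
#' @param tidal_volume_l Tidal volume, litres (> 0); default 0.45.
#' @return Minute volume in litres/min.
#' @export
minute_volume <- function(rr, tidal_volume_l = 0.45) {
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop_domain("respiratory rate must be > 0")
  }
  if (any(!is.finite(tidal_volume_l)) || any(tidal_volume_l <= 0)) {
    stop_domain("tidal volume must be > 0")
  }
  rr * tidal_volume_l
}

# Dilution formula: supplemental oxygen plus entrained room air (21%),
# divided by total minute volume.
fio2_dilution <- function(flow_lpm, rr, tidal_volume_l = 0.45) {
  mv <- minute_volume(rr, tidal_volume_l)
  (flow_lpm + 0.21 * (mv - flow_lpm)) / mv
}

#' Estimate inspired oxygen fraction for observation sets
#'
#' Computes `calculated_fio2` for every row: 0.21 on room air; the dilution
#' formula `(flow + 0.21 * (MV - flow)) / MV` (minute volume MV from the
#' respiratory rate at a fixed tidal volume) for variable-performance
#' devices; the prescribed value for fixed-performance masks; and an assumed
#' maximum of 1.0 for high-flow nasal oxygen and non-invasive ventilation.
#' Raw formula values outside `[0.21, 1.0]` (possible when flow exceeds
#' minute volume) are clamped and flagged.
#'
#' @param obs Data frame of observations (needs `device`, `rr`, and
#'   `o2_flow_lpm` / `prescribed_fio2` where the device requires them).
#' @param device_table Device behaviour table, see [default_device_table()].
#' @param tidal_volume_l Fixed tidal volume, litres; default 0.45.
#' @return The input as a tibble with columns `calculated_fio2` (fraction in
#'   `[0.21, 1.0]`), `fio2_method` (`room_air`, `formula`, `prescribed`,
#'   `saturated_max`) and `fio2_clamped` (logical) appended.
#' @examples
#' obs <- tibble::tibble(device = "nasal_cannula", rr = 18, o2_flow_lpm = 2,
#'                       prescribed_fio2 = NA_real_)
#' estimate_fio2(obs)$calculated_fio2  # (2 + 0.21 * 6.1) / 8.1
#' @export
estimate_fio2 <- function(obs, device_table = default_device_table(),
                          tidal_volume_l = 0.45) {
  obs <- as_tibble(obs)
  if (!"device" %in% names(obs)) stop_input("observations need a device column")
  unknown <- setdiff(unique(obs$device[!is.na(obs$device)]), device_table$device)
  if (length(unknown) > 0) {
    stop_input(paste0("device(s) not in device table: ",
                      paste(unknown, collapse = ", ")))
  }
  behaviour <- device_table$behaviour[match(obs$device, device_table$device)]

  n <- nrow(obs)
  fio2 <- rep(NA_real_, n)
  method <- rep(NA_character_, n)
  clamped <- rep(FALSE, n)

  is_room <- !is.na(behaviour) & behaviour == "room_air"
  fio2[is_room] <- 0.21
  method[is_room] <- "room_air"

  is_max <- !is.na(behaviour) & behaviour == "saturated_max"
  fio2[is_max] <- 1.0
  method[is_max] <- "saturated_max"

  is_rx <- !is.na(behaviour) & behaviour == "prescribed"
  if (any(is_rx)) {
    if (!"prescribed_fio2" %in% names(obs) || anyNA(obs$prescribed_fio2[is_rx])) {
      stop_input("fixed-performance mask rows need prescribed_fio2")
    }
    fio2[is_rx] <- obs$prescribed_fio2[is_rx]
    method[is_rx] <- "prescribed"
  }

  is_form <- !is.na(behaviour) & behaviour == "formula"
  if (any(is_form)) {
    if (!all(c("o2_flow_lpm", "rr") %in% names(obs)) ||
        anyNA(obs$o2_flow_lpm[is_form])) {
      stop_input("formula devices need o2_flow_lpm and rr")
    }
    if (anyNA(obs$rr[is_form]) || any(obs$rr[is_form] <= 0)) {
      stop_domain("formula devices need respiratory rate > 0")
    }
    raw <- fio2_dilution(obs$o2_flow_lpm[is_form], obs$rr[is_form],
                         tidal_volume_l)
    clamped[is_form] <- raw < 0.21 | raw > 1.0
    fio2[is_form] <- pmin(pmax(raw, 0.21), 1.0)
    method[is_form] <- "formula"
  }

  obs$calculated_fio2 <- fio2
  obs$fio2_method <- method
  obs$fio2_clamped <- clamped
  obs
}

#' Sensitivity of estimated FiO2 to the fixed tidal-volume assumption
#'
#' Recomputes [estimate_fio2()] across a grid of tidal volumes. For formula
#' devices at fixed flow the estimate decreases as the assumed tidal volume
#' (hence minute volume) grows; room-air, prescribed and saturated devices
#' are unaffected.
#'
#' @inheritParams estimate_fio2
#' @param vt_grid Tidal volumes (litres) to evaluate; default 0.30-0.70 L in
#'   0.05 L steps.
#' @return Long tibble with `.row` (input row), `tidal_volume_l` and
#'   `calculated_fio2`.
#' @export
tidal_volume_sensitivity <- function(obs, device_table = default_device_table(),
                                     vt_grid = seq(0.30, 0.70, by = 0.05)) {
  if (length(vt_grid) == 0 || any(!is.finite(vt_grid)) || any(vt_grid <= 0)) {
    stop_domain("vt_grid must be non-empty and positive")
  }
  purrr::map_dfr(vt_grid, function(vt) {
    est <- estimate_fio2(obs, device_table, tidal_volume_l = vt)
    tibble(.row = seq_len(nrow(est)), tidal_volume_l = vt,
           calculated_fio2 = est$calculated_fio2)
  })
}
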
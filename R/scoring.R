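#' NEWS score chart
#'
#' Per-vital scoring bands for the National Early Warning Score. Each vital
#' is a list with `breaks` (internal cut-points; intervals are right-closed,
#' `(b[i], b[i+1]]`) and `weights` (one more weight than breaks, each in
#' 0-3). The default encodes the published RCP NEWS (2012) chart: this chart
#' is configuration shipped for convenience and should be verified against
#' the RCP publication before clinical use. The oxygen item of plain NEWS is
#' binary: 0 on room air, 2 on any supplemental oxygen.
#'
#' @param rr,spo2,temp,sbp,hr Optional replacement band definitions,
#'   each `list(breaks = ..., weights = ...)`.
#' @param consciousness_weights Named weights for AVPU levels.
#' @param oxygen_supplemental_weight Weight for the binary oxygen item when
#'   any supplemental device is in use; default 2.
#' @return An object of class `news_chart`.
#' @export
news_chart <- function(rr = NULL, spo2 = NULL, temp = NULL, sbp = NULL,
                       hr = NULL, consciousness_weights = NULL,
                       oxygen_supplemental_weight = 2) {
  chart <- list(
    rr   = rr   %||% list(breaks = c(8, 11, 20, 24),        weights = c(3, 1, 0, 2, 3)),
    spo2 = spo2 %||% list(breaks = c(91, 93, 95),           weights = c(3, 2, 1, 0)),
    temp = temp %||% list(breaks = c(35.0, 36.0, 38.0, 39.0), weights = c(3, 1, 0, 1, 2)),
    sbp  = sbp  %||% list(breaks = c(90, 100, 110, 219),    weights = c(3, 2, 1, 0, 3)),
    hr   = hr   %||% list(breaks = c(40, 50, 90, 110, 130), weights = c(3, 1, 0, 1, 2, 3)),
    consciousness_weights = consciousness_weights %||%
      c(A = 0, V = 3, P = 3, U = 3),
    oxygen_supplemental_weight = oxygen_supplemental_weight
  )
  validate_news_chart(chart)
  structure(chart, class = "news_chart")
}

validate_news_chart <- function(chart) {
  for (v in c("rr", "spo2", "temp", "sbp", "hr")) {
    b <- chart[[v]]$breaks
    w <- chart[[v]]$weights
    if (is.unsorted(b, strictly = TRUE)) {
      stop_input(paste0(v, " breaks must be strictly ascending"))
    }
    if (length(w) != length(b) + 1) {
      stop_input(paste0(v, " needs one more weight than breaks"))
    }
    if (any(w < 0 | w > 3 | w != floor(w))) {
      stop_input(paste0(v, " weights must be integers in 0-3"))
    }
  }
  if (!all(avpu_levels() %in% names(chart$consciousness_weights))) {
    stop_input("consciousness weights must cover A, V, P, U")
  }
  invisible(chart)
}

# weight of x under a right-closed banded partition
band_weight <- function(x, breaks, weights) {
  weights[findInterval(x, breaks, left.open = TRUE) + 1L]
}

#' FiO2 scoring bands
#'
#' Three ascending cut-points partitioning the inspired-oxygen range
#' `[0.21, 1.0]` into four bands weighted 0/1/2/3 as the concentration
#' increases. Band semantics are right-closed: `[0.21, c1]`, `(c1, c2]`,
#' `(c2, c3]`, `(c3, 1.0]`. The defaults 0.22 / 0.37 / 0.53 reproduce the
#' published band edges (in percent: 21-22, 22.1-37, 37.1-53, >53); the
#' weight-2 band is the one equivalent to the flat score NEWS gives any
#' patient on oxygen.
#'
#' @param cut_points Three strictly ascending fractions in (0.21, 1.0).
#' @return An object of class `fio2_bands`.
#' @export
fio2_bands <- function(cut_points = c(0.22, 0.37, 0.53)) {
  cut_points <- as.numeric(cut_points)
  if (length(cut_points) != 3 || anyNA(cut_points) ||
      is.unsorted(cut_points, strictly = TRUE) ||
      cut_points[1] <= 0.21 || cut_points[3] >= 1.0) {
    stop_input("cut_points must be three strictly ascending fractions in (0.21, 1.0)")
  }
  structure(list(cut_points = cut_points, weights = 0:3),
            class = "fio2_bands")
}

#' @export
print.fio2_bands <- function(x, ...) {
  pct <- round(100 * x$cut_points, 1)
  cat("FiO2 scoring bands (percent):\n")
  labs <- c(paste0("21-", pct[1]), paste0(">", pct[1], "-", pct[2]),
            paste0(">", pct[2], "-", pct[3]), paste0(">", pct[3]))
  for (i in 1:4) cat(sprintf("  weight %d: %s\n", x$weights[i], labs[i]))
  invisible(x)
}

#' Band weight of an inspired oxygen fraction
#'
#' @param fio2 Fractions in `[0.21, 1.0]` (vectorised).
#' @param bands A [fio2_bands()] object.
#' @return Integer weights in 0-3.
#' @export
assign_band <- function(fio2, bands = fio2_bands()) {
  if (any(!is.finite(fio2)) || any(fio2 < 0.21 - 1e-12) || any(fio2 > 1 + 1e-12)) {
    stop_domain("fio2 must lie in [0.21, 1.0]")
  }
  as.integer(band_weight(fio2, bands$cut_points, bands$weights))
}

consciousness_score <- function(obs, chart, gcs_map) {
  avpu <- if ("avpu" %in% names(obs)) obs$avpu else rep(NA_character_, nrow(obs))
  need_gcs <- is.na(avpu)
  if (any(need_gcs)) {
    if (!"gcs" %in% names(obs) || anyNA(obs$gcs[need_gcs])) {
      stop_input("rows without AVPU need a GCS value")
    }
    avpu[need_gcs] <- gcs_to_avpu(obs$gcs[need_gcs], gcs_map)
  }
  unname(chart$consciousness_weights[avpu])
}

score_common <- function(obs, chart, gcs_map) {
  needed <- c("hr", "rr", "sbp", "spo2", "temp", "device")
  miss <- setdiff(needed, names(obs))
  if (length(miss) > 0) {
    stop_input(paste0("observations missing column(s): ",
                      paste(miss, collapse = ", ")))
  }
  vals <- obs[, needed[1:5]]
  if (anyNA(vals) || anyNA(obs$device)) {
    stop_input("scoring requires complete observation sets; run completeness_filter() first")
  }
  tibble(
    score_rr   = band_weight(obs$rr,   chart$rr$breaks,   chart$rr$weights),
    score_spo2 = band_weight(obs$spo2, chart$spo2$breaks, chart$spo2$weights),
    score_temp = band_weight(obs$temp, chart$temp$breaks, chart$temp$weights),
    score_sbp  = band_weight(obs$sbp,  chart$sbp$breaks,  chart$sbp$weights),
    score_hr   = band_weight(obs$hr,   chart$hr$breaks,   chart$hr$weights),
    score_consciousness = consciousness_score(obs, chart, gcs_map)
  )
}

#' Score observation sets with NEWS
#'
#' Sums per-vital sub-scores from the chart bands plus the binary oxygen
#' item (0 on room air, 2 on any supplemental device, by default). Requires
#' complete observation sets.
#'
#' @param obs Data frame of complete observations.
#' @param chart A [news_chart()].
#' @param gcs_map GCS-to-AVPU map used when AVPU is absent,
#'   see [default_gcs_avpu_map()].
#' @return Input tibble with per-component `score_*` columns and
#'   `news_total` appended.
#' @export
score_news <- function(obs, chart = news_chart(),
                       gcs_map = default_gcs_avpu_map()) {
  obs <- as_tibble(obs)
  sub <- score_common(obs, chart, gcs_map)
  sub$score_oxygen <- if_else(obs$device == "room_air", 0,
                              as.numeric(chart$oxygen_supplemental_weight))
  out <- dplyr::bind_cols(obs[, setdiff(names(obs), names(sub))], sub)
  out$news_total <- as.integer(rowSums(sub))
  out
}

#' Score observation sets with NEWS-FiO2
#'
#' Identical to [score_news()] except the binary oxygen item is replaced by
#' the graded weight of the calculated inspired oxygen fraction under the
#' FiO2 bands, so escalating oxygen therapy raises the score. Room air
#' (FiO2 0.21) falls in the weight-0 band, as do very dilute low-flow
#' estimates up to the first cut-point.
#'
#' @inheritParams score_news
#' @param bands A [fio2_bands()] object.
#' @param fio2_col Name of the column holding the calculated FiO2 fraction;
#'   default `"calculated_fio2"` as produced by [estimate_fio2()].
#' @return Input tibble with the vital sub-scores, the graded oxygen item
#'   `score_fio2` and `newsfio2_total` appended. Applying both scoring
#'   functions to the same table keeps one copy of the shared vital
#'   sub-scores plus both oxygen items and totals.
#' @export
score_news_fio2 <- function(obs, chart = news_chart(), bands = fio2_bands(),
                            fio2_col = "calculated_fio2",
                            gcs_map = default_gcs_avpu_map()) {
  obs <- as_tibble(obs)
  if (!fio2_col %in% names(obs)) {
    stop_input(paste0("missing FiO2 column '", fio2_col,
                      "'; run estimate_fio2() first"))
  }
  if (anyNA(obs[[fio2_col]])) stop_input("calculated FiO2 contains missing values")
  sub <- score_common(obs, chart, gcs_map)
  sub$score_fio2 <- as.numeric(assign_band(obs[[fio2_col]], bands))
  out <- dplyr::bind_cols(obs[, setdiff(names(obs), names(sub))], sub)
  out$newsfio2_total <- as.integer(rowSums(sub))
  out
}

# ---- serialisation ---------------------------------------------------------

#' Read / write FiO2 bands as YAML configuration
#'
#' @param path YAML file path.
#' @param bands A [fio2_bands()] object.
#' @return `read_fio2_bands()` returns a [fio2_bands()] object;
#'   `write_fio2_bands()` returns `path` invisibly.
#' @export
read_fio2_bands <- function(path) {
  cfg <- read_schema_config(path)
  fio2_bands(cut_points = unlist(cfg$cut_points))
}

#' @rdname read_fio2_bands
#' @export
write_fio2_bands <- function(bands, path) {
  yaml::write_yaml(list(cut_points = as.numeric(bands$cut_points),
                        weights = as.integer(bands$weights)), path)
  invisible(path)
}

#' Read / write a NEWS score chart as YAML configuration
#'
#' @param path YAML file path.
#' @param chart A [news_chart()] object.
#' @return `read_news_chart()` returns a `news_chart`;
#'   `write_news_chart()` returns `path` invisibly.
#' @export
read_news_chart <- function(path) {
  cfg <- read_schema_config(path)
  news_chart(rr = cfg$rr, spo2 = cfg$spo2, temp = cfg$temp, sbp = cfg$sbp,
             hr = cfg$hr,
             consciousness_weights = unlist(cfg$consciousness_weights) %||% NULL,
             oxygen_supplemental_weight = cfg$oxygen_supplemental_weight %||% 2)
}

#' @rdname read_news_chart
#' @export
write_news_chart <- function(chart, path) {
  out <- unclass(chart)
  out$consciousness_weights <- as.list(out$consciousness_weights)
  yaml::write_yaml(out, path)
  invisible(path)
}
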
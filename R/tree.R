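#' Configuration for FiO2 threshold derivation
#'
#' @param max_cut_points Number of cut-points (internal tree splits) to
#'   derive; default 3, giving four bands weighted 0-3.
#' @param min_leaf_fraction Minimum fraction of observations per leaf;
#'   default 0.01. Guards against sliver bands driven by a handful of rows.
#' @param rounding Decimal places for reported percent thresholds; default 1
#'   (internal cut-points stay unrounded).
#' @return List of class `tree_config`.
#' @export
tree_config <- function(max_cut_points = 3, min_leaf_fraction = 0.01,
                        rounding = 1) {
  if (max_cut_points < 1) stop_input("max_cut_points must be >= 1")
  if (min_leaf_fraction <= 0 || min_leaf_fraction >= 0.5) {
    stop_input("min_leaf_fraction must be in (0, 0.5)")
  }
  structure(list(max_cut_points = max_cut_points,
                 min_leaf_fraction = min_leaf_fraction,
                 rounding = rounding),
            class = "tree_config")
}

# Gini impurity mass of a node, in count units: n * gini = 2 * pos * neg / n.
gini_mass <- function(n, pos) {
  ifelse(n == 0, 0, 2 * pos * (n - pos) / n)
}

# Best split of sorted leaf [lo, hi]: returns (gain, cut, index) or NULL.
# cy is the cumulative positive count over the sorted fio2 vector x.
best_leaf_split <- function(x, cy, lo, hi, min_n) {
  if (hi - lo < 1) return(NULL)
  i <- lo:(hi - 1)
  valid <- x[i] < x[i + 1]
  n <- hi - lo + 1
  nl <- i - lo + 1
  valid <- valid & nl >= min_n & (n - nl) >= min_n
  if (!any(valid)) return(NULL)
  i <- i[valid]
  nl <- nl[valid]
  base <- if (lo > 1) cy[lo - 1] else 0
  posl <- cy[i] - base
  pos <- cy[hi] - base
  gain <- gini_mass(n, pos) - gini_mass(nl, posl) - gini_mass(n - nl, pos - posl)
  # ties in gain break toward the lower FiO2 cut (i is ascending in x)
  k <- which.max(gain)
  list(gain = gain[k], cut = (x[i[k]] + x[i[k] + 1]) / 2, index = i[k])
}

#' Derive FiO2 scoring bands with a single-feature classification tree
#'
#' Greedy CART growth restricted to the calculated FiO2 feature against the
#' binary event label: at each step the split (over any current leaf)
#' maximising the decrease in Gini impurity mass is taken, subject to the
#' minimum leaf fraction, until `max_cut_points` internal splits exist. The
#' split thresholds, sorted ascending, become the band cut-points and the
#' weights 0-3 are assigned in ascending FiO2 order (as the concentration
#' increases), not by re-ranking event rates; a diagnostic reports whether
#' event rates are in fact monotone across the bands. Gain ties break toward
#' the lower FiO2 cut, so derivation is deterministic.
#'
#' @param labeled Data frame with a calculated FiO2 column and a logical
#'   event-label column.
#' @param config A [tree_config()].
#' @param fio2_col,label_col Column names; defaults `"calculated_fio2"`,
#'   `"label"`.
#' @return Object of class `fio2_band_fit`: `bands` (a [fio2_bands()] when
#'   `max_cut_points == 3`, else the raw cut-points), `cut_points`,
#'   `splits` (order found, cut, impurity gain), `band_summary` (per-band
#'   counts and event rates), `monotone_event_rate`, `n`, `n_events`.
#'   Methods: [tidy()], [glance()], `print`.
#' @export
derive_fio2_bands <- function(labeled, config = tree_config(),
                              fio2_col = "calculated_fio2",
                              label_col = "label") {
  labeled <- as_tibble(labeled)
  for (col in c(fio2_col, label_col)) {
    if (!col %in% names(labeled)) stop_input(paste0("missing column '", col, "'"))
  }
  x <- labeled[[fio2_col]]
  y <- as.logical(labeled[[label_col]])
  if (anyNA(x) || anyNA(y)) stop_input("FiO2 and label must be complete")
  n <- length(x)
  if (n == 0) stop_input("no observations", class = "newsfio2_derivation_error")
  if (length(unique(y)) < 2) {
    stop_input("labels contain a single class; cannot derive thresholds",
               class = "newsfio2_derivation_error")
  }
  if (length(unique(x)) <= config$max_cut_points) {
    stop_input("fewer distinct FiO2 values than required cut-points",
               class = "newsfio2_derivation_error")
  }

  ord <- order(x)
  xs <- x[ord]
  cy <- cumsum(as.numeric(y[ord]))
  min_n <- max(1L, ceiling(config$min_leaf_fraction * n))

  leaves <- list(c(1L, n))
  splits <- tibble(order = integer(), cut = numeric(), gain = numeric())
  while (nrow(splits) < config$max_cut_points) {
    cands <- purrr::compact(purrr::map(leaves, function(lf) {
      best_leaf_split(xs, cy, lf[1], lf[2], min_n)
    }))
    if (length(cands) == 0) break
    gains <- purrr::map_dbl(cands, "gain")
    cuts <- purrr::map_dbl(cands, "cut")
    best <- order(-gains, cuts)[1]  # tie -> lower cut
    pick <- cands[[best]]
    leaf_i <- which(purrr::map_lgl(leaves, function(lf) {
      lf[1] <= pick$index && pick$index < lf[2]
    }))[1]
    lf <- leaves[[leaf_i]]
    leaves[[leaf_i]] <- c(lf[1], pick$index)
    leaves[[length(leaves) + 1]] <- c(pick$index + 1L, lf[2])
    splits <- bind_rows(splits, tibble(order = nrow(splits) + 1L,
                                       cut = pick$cut,
                                       gain = pick$gain / n))
  }
  if (nrow(splits) < config$max_cut_points) {
    stop_input(paste0("minimum leaf size binds before ", config$max_cut_points,
                      " cut-points could be derived"),
               class = "newsfio2_derivation_error")
  }

  cuts <- sort(splits$cut)
  bands <- if (config$max_cut_points == 3 &&
               cuts[1] > 0.21 && cuts[3] < 1.0) fio2_bands(cuts) else NULL
  weights <- 0:config$max_cut_points
  band_idx <- findInterval(x, cuts, left.open = TRUE) + 1L
  summ <- tibble(
    weight = weights,
    fio2_low = c(min(0.21, min(x)), cuts),
    fio2_high = c(cuts, max(1.0, max(x))),
    n_obs = as.integer(tabulate(band_idx, nbins = length(weights))),
    n_events = purrr::map_int(seq_along(weights), function(b) sum(y[band_idx == b]))
  )
  summ$event_rate <- ifelse(summ$n_obs > 0, summ$n_events / summ$n_obs, NA_real_)
  rates <- summ$event_rate[!is.na(summ$event_rate)]
  monotone <- !is.unsorted(rates)
  if (!monotone) {
    warn("event rate is not monotone across the derived FiO2 bands")
  }
  total_gain <- sum(splits$gain)
  gain_fraction <- total_gain / (gini_mass(n, sum(y)) / n)
  if (gain_fraction < 0.01) {
    warn("near-zero impurity gain: FiO2 carries little information about the label")
  }

  structure(list(
    bands = bands,
    cut_points = cuts,
    cut_points_pct = round(100 * cuts, config$rounding),
    splits = splits,
    band_summary = summ,
    monotone_event_rate = monotone,
    total_gain = total_gain,
    gain_fraction = gain_fraction,
    n = n,
    n_events = sum(y),
    config = config
  ), class = "fio2_band_fit")
}

#' @export
print.fio2_band_fit <- function(x, ...) {
  cat("FiO2 band derivation (single-feature Gini tree)\n")
  cat(sprintf("  n = %d observations, %d events (%.2f%%)\n", x$n, x$n_events,
              100 * x$n_events / x$n))
  cat("  cut-points (%):", paste(x$cut_points_pct, collapse = ", "), "\n")
  cat(sprintf("  total impurity gain: %.5f; event rate monotone: %s\n",
              x$total_gain, x$monotone_event_rate))
  print(x$band_summary)
  invisible(x)
}

#' Tidy a FiO2 band fit
#'
#' @param x A `fio2_band_fit` from [derive_fio2_bands()].
#' @param ... Unused.
#' @return Per-band counts and event rates as a tibble.
#' @method tidy fio2_band_fit
#' @export
tidy.fio2_band_fit <- function(x, ...) x$band_summary

#' One-row summary of a FiO2 band fit
#'
#' @inheritParams tidy.fio2_band_fit
#' @return One-row tibble with the cut-points and fit diagnostics.
#' @method glance fio2_band_fit
#' @export
glance.fio2_band_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         cut1 = x$cut_points[1], cut2 = x$cut_points[2], cut3 = x$cut_points[3],
         total_gain = x$total_gain,
         monotone_event_rate = x$monotone_event_rate)
}

#' Per-band observation and event tallies
#'
#' Counts observation sets and event-labelled observation sets falling in
#' each FiO2 scoring band, with event rates and the share of all
#' observations per band. Counts conserve: they sum to the input size and
#' total events.
#'
#' @param labeled Data frame with calculated FiO2 and (optionally) a logical
#'   label column; without labels, event columns are zero.
#' @param bands A [fio2_bands()] object.
#' @param fio2_col,label_col Column names.
#' @return Tibble with one row per band: `weight`, `fio2_range_pct`,
#'   `n_obs`, `n_events`, `event_rate`, `pct_obs`.
#' @export
band_report <- function(labeled, bands = fio2_bands(),
                        fio2_col = "calculated_fio2", label_col = "label") {
  labeled <- as_tibble(labeled)
  if (!fio2_col %in% names(labeled)) stop_input(paste0("missing column '", fio2_col, "'"))
  fio2 <- labeled[[fio2_col]]
  lab <- if (label_col %in% names(labeled)) as.logical(labeled[[label_col]]) else rep(FALSE, length(fio2))
  w <- if (length(fio2) > 0) assign_band(fio2, bands) else integer()
  pct <- round(100 * bands$cut_points, 1)
  ranges <- c(paste0("21-", pct[1]),
              paste0(">", pct[1], "-", pct[2]),
              paste0(">", pct[2], "-", pct[3]),
              paste0(">", pct[3]))
  out <- tibble(
    weight = bands$weights,
    fio2_range_pct = ranges,
    n_obs = as.integer(tabulate(w + 1L, nbins = 4)),
    n_events = purrr::map_int(bands$weights, function(b) sum(lab[w == b]))
  )
  out$event_rate <- ifelse(out$n_obs > 0, out$n_events / out$n_obs, NA_real_)
  total <- sum(out$n_obs)
  out$pct_obs <- if (total > 0) 100 * out$n_obs / total else rep(NA_real_, 4)
  out
}
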
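check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop_input("labels must be complete TRUE/FALSE")
  if (!any(labels) || all(labels)) {
    stop_input("both classes must be present to compute discrimination",
               class = "newsfio2_undefined_metric")
  }
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random event observation
#' outscores a random non-event observation, with ties counted one half.
#' Computed from midranks, so it is exact under ties and invariant to any
#' strictly increasing transform of the scores.
#'
#' @param scores Numeric scores (higher = more at risk).
#' @param labels Logical event labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  if (length(scores) != length(labels)) stop_input("scores and labels differ in length")
  if (anyNA(scores)) stop_input("scores must be complete")
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified percentile bootstrap confidence interval for AUROC
#'
#' Resamples events and non-events separately with replacement (preserving
#' the event prevalence exactly in every replicate) and takes percentile
#' bounds of the replicate AUROCs.
#'
#' @inheritParams auroc
#' @param reps Bootstrap replicates; default 1000.
#' @param seed Optional integer; when given, results are reproducible and
#'   the caller's random stream is left untouched.
#' @param conf Confidence level; default 0.95.
#' @return Tibble with `auroc`, `ci_low`, `ci_high`, `reps`.
#' @export
bootstrap_auroc_ci <- function(scores, labels, reps = 1000, seed = NULL,
                               conf = 0.95) {
  labels <- check_two_classes(labels)
  if (reps < 2) stop_input("reps must be >= 2")
  pos <- scores[labels]
  neg <- scores[!labels]
  n_pos <- length(pos)
  n_neg <- length(neg)
  lab_boot <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  stats <- with_preserved_seed(seed, {
    purrr::map_dbl(seq_len(reps), function(i) {
      auroc(c(pos[sample.int(n_pos, n_pos, replace = TRUE)],
              neg[sample.int(n_neg, n_neg, replace = TRUE)]),
            lab_boot)
    })
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(stats, c(alpha, 1 - alpha), type = 7))
  tibble(auroc = auroc(scores, labels), ci_low = ci[1], ci_high = ci[2],
         reps = reps)
}

#' Operating-point metrics at an alert threshold
#'
#' An observation alerts when its score is at or above the threshold.
#' Sensitivity, specificity and positive predictive value are reported in
#' percent, along with efficiency: the percentage of *all* observation sets
#' that alert, a ward-workload proxy.
#'
#' @inheritParams auroc
#' @param threshold Integer alert threshold (alert when score >= threshold).
#' @return One-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `efficiency` (all percentages).
#'   With no alerts at the threshold, `ppv` is `NA` with a warning.
#' @export
operating_point <- function(scores, labels, threshold) {
  labels <- check_two_classes(labels)
  alert <- scores >= threshold
  tp <- sum(alert & labels)
  fp <- sum(alert & !labels)
  fn <- sum(!alert & labels)
  tn <- sum(!alert & !labels)
  ppv <- if (tp + fp == 0) {
    warn(paste0("no alerts at threshold ", threshold, "; PPV undefined"))
    NA_real_
  } else 100 * tp / (tp + fp)
  tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         ppv = ppv,
         efficiency = 100 * (tp + fp) / length(labels))
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return Tibble with `threshold`, `fpr`, `tpr` at every distinct score,
#'   descending threshold (so fpr/tpr are non-decreasing).
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_two_classes(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  purrr::map_dfr(thr, function(t) {
    alert <- scores >= t
    tibble(threshold = t,
           fpr = sum(alert & !labels) / n_neg,
           tpr = sum(alert & labels) / n_pos)
  })
}

#' Precision-recall curve
#'
#' Precision (PPV) and recall (sensitivity) at each distinct score
#' threshold, descending. Preferred over ROC display at low prevalence
#' because it ignores the mass of correctly unremarkable observations.
#'
#' @inheritParams auroc
#' @return Tibble with `threshold`, `recall`, `precision` (fractions).
#' @export
pr_curve <- function(scores, labels) {
  labels <- check_two_classes(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  purrr::map_dfr(thr, function(t) {
    alert <- scores >= t
    tp <- sum(alert & labels)
    tibble(threshold = t, recall = tp / n_pos, precision = tp / sum(alert))
  })
}

#' Efficiency curve
#'
#' For each distinct score value: the fraction of all observation sets at
#' or above that value (workload) against the fraction of event-labelled
#' observation sets at or above it (capture). At the minimum score both
#' fractions are 1.
#'
#' @inheritParams auroc
#' @return Tibble with `threshold`, `obs_fraction`, `event_fraction`. If no
#'   labels are positive, `event_fraction` is `NA` with a warning.
#' @export
efficiency_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n <- length(scores)
  n_pos <- sum(labels)
  if (n_pos == 0) warn("no event observations; event_fraction undefined")
  purrr::map_dfr(thr, function(t) {
    alert <- scores >= t
    tibble(threshold = t,
           obs_fraction = sum(alert) / n,
           event_fraction = if (n_pos > 0) sum(alert & labels) / n_pos else NA_real_)
  })
}

#' AUROC as the time-to-event window shrinks
#'
#' Recomputes AUROC for a sequence of look-back windows from the full
#' window down toward zero. The negative set is fixed (all event-free
#' observations); the positive set at window `w` is the event-labelled
#' observations within `w` hours of their event, so it shrinks with `w`.
#' Windows with no positives are reported as `NA`.
#'
#' @param data Data frame with score, label and time-to-event columns, as
#'   produced by [tag_events()] plus a scoring function.
#' @param score_col Name of the score column.
#' @param windows Window lengths in hours, descending; default 24 down to 0
#'   in steps of 4.
#' @param label_col,tte_col Column names for the label and time-to-event.
#' @return Tibble with `window_h`, `auroc`, `n_pos`.
#' @export
auroc_by_window <- function(data, score_col, windows = seq(24, 0, by = -4),
                            label_col = "label", tte_col = "time_to_event_h") {
  data <- as_tibble(data)
  lab <- check_two_classes(data[[label_col]])
  s <- data[[score_col]]
  tte <- data[[tte_col]]
  neg <- !lab
  purrr::map_dfr(windows, function(w) {
    pos <- lab & !is.na(tte) & tte <= w
    n_pos <- sum(pos)
    a <- if (n_pos == 0) NA_real_ else {
      keep <- pos | neg
      auroc(s[keep], pos[keep])
    }
    tibble(window_h = w, auroc = a, n_pos = n_pos)
  })
}

#' Evaluate an early warning score against the event label
#'
#' Bundles every discrimination and workload measure into one report:
#' AUROC with a stratified bootstrap confidence interval, operating points
#' at the requested alert thresholds, and ROC, precision-recall, efficiency
#' and AUROC-versus-window curves.
#'
#' @param data Labelled, scored observations (needs the score column,
#'   `label`, and `time_to_event_h` for the window curve).
#' @param score_col Name of the score column, e.g. `"news_total"`.
#' @param thresholds Alert thresholds for operating points; default `c(5, 7)`.
#' @param reps Bootstrap replicates; default 1000.
#' @param seed Optional seed for the bootstrap.
#' @param windows Windows (hours) for [auroc_by_window()]; `NULL` to skip.
#' @return Object of class `ews_evaluation` with elements `auroc`, `ci_low`,
#'   `ci_high`, `operating_points`, `roc_curve`, `pr_curve`,
#'   `efficiency_curve`, `auroc_by_window`, `n_observations`, `n_events`,
#'   `score_name`. Methods: [tidy()] (operating points), [glance()]
#'   (one-row summary), [autoplot()], `print`.
#' @export
evaluate_score <- function(data, score_col, thresholds = c(5, 7),
                           reps = 1000, seed = NULL,
                           windows = seq(24, 0, by = -4)) {
  data <- as_tibble(data)
  if (!score_col %in% names(data)) {
    stop_input(paste0("missing score column '", score_col, "'"))
  }
  s <- data[[score_col]]
  lab <- check_two_classes(data$label)
  ci <- bootstrap_auroc_ci(s, lab, reps = reps, seed = seed)
  abw <- if (!is.null(windows) && "time_to_event_h" %in% names(data)) {
    auroc_by_window(data, score_col, windows)
  } else NULL
  structure(list(
    auroc = ci$auroc,
    ci_low = ci$ci_low,
    ci_high = ci$ci_high,
    bootstrap_reps = reps,
    operating_points = purrr::map_dfr(thresholds, function(t) {
      operating_point(s, lab, t)
    }),
    roc_curve = roc_curve(s, lab),
    pr_curve = pr_curve(s, lab),
    efficiency_curve = efficiency_curve(s, lab),
    auroc_by_window = abw,
    n_observations = length(s),
    n_events = sum(lab),
    score_name = score_col
  ), class = "ews_evaluation")
}

#' @export
print.ews_evaluation <- function(x, ...) {
  cat(sprintf("Early warning score evaluation: %s\n", x$score_name))
  cat(sprintf("  %d observation sets, %d event-labelled (%.1f%%)\n",
              x$n_observations, x$n_events,
              100 * x$n_events / x$n_observations))
  cat(sprintf("  AUROC %.3f (95%% CI %.3f-%.3f, %d bootstrap reps)\n",
              x$auroc, x$ci_low, x$ci_high, x$bootstrap_reps))
  op <- x$operating_points
  for (i in seq_len(nrow(op))) {
    cat(sprintf("  score >= %d: sens %.1f%%, spec %.1f%%, PPV %s, efficiency %.1f%%\n",
                op$threshold[i], op$sensitivity[i], op$specificity[i],
                ifelse(is.na(op$ppv[i]), "NA", sprintf("%.1f%%", op$ppv[i])),
                op$efficiency[i]))
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `ews_evaluation` from [evaluate_score()].
#' @param ... Unused.
#' @return The operating points as a tibble, one row per alert threshold.
#' @method tidy ews_evaluation
#' @export
tidy.ews_evaluation <- function(x, ...) {
  dplyr::bind_cols(tibble(score = x$score_name), x$operating_points)
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.ews_evaluation
#' @return One-row tibble with AUROC, its confidence interval and sizes.
#' @method glance ews_evaluation
#' @export
glance.ews_evaluation <- function(x, ...) {
  tibble(score = x$score_name, auroc = x$auroc, ci_low = x$ci_low,
         ci_high = x$ci_high, n_observations = x$n_observations,
         n_events = x$n_events)
}
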
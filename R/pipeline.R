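#' Run the full synthetic study end to end
#'
#' Convenience wrapper chaining every stage on generated data: simulate a
#' ward cohort, apply eligibility filters, estimate FiO2, label
#' observations against the 24-hour composite outcome, derive FiO2 bands
#' from the labelled oxygen-cohort observations, score with NEWS and
#' NEWS-FiO2, and evaluate both scores. Mirrors the two-database design by
#' deriving bands on one generated cohort and evaluating on a second,
#' independently generated one.
#'
#' @param config A [sim_config()] for the evaluation cohort; the derivation
#'   cohort uses the same configuration with a shifted seed.
#' @param thresholds Alert thresholds for operating points.
#' @param reps Bootstrap replicates for the AUROC confidence intervals.
#' @return List with `band_fit`, `bands`, `eval_news`, `eval_news_fio2`,
#'   `scored` (the labelled, scored oxygen-cohort observations of the
#'   evaluation cohort) and `exclusions`.
#' @export
run_synthetic_study <- function(config = sim_config(seed = 1),
                                thresholds = c(5, 7), reps = 200) {
  derive_cfg <- config
  derive_cfg$seed <- if (is.null(config$seed)) NULL else config$seed + 1000L

  prep <- function(cfg) {
    cohort <- generate_cohort(cfg)
    elig <- filter_eligible(cohort$admissions, cohort$observations)
    est <- estimate_fio2(elig$observations)
    labeled <- tag_events(est, elig$admissions)
    # oxygen-requiring cohort: admissions with any supplemental-oxygen set
    ox_adm <- unique(labeled$admission_id[labeled$device != "room_air"])
    list(oxygen = labeled[labeled$admission_id %in% ox_adm, ],
         all = labeled, exclusions = elig$exclusions)
  }

  train <- prep(derive_cfg)
  fit <- derive_fio2_bands(train$oxygen)

  test <- prep(config)
  scored <- score_news(test$oxygen)
  scored <- score_news_fio2(scored, bands = fit$bands)
  seed_eval <- if (is.null(config$seed)) NULL else config$seed + 2000L
  list(
    band_fit = fit,
    bands = fit$bands,
    eval_news = evaluate_score(scored, "news_total", thresholds = thresholds,
                               reps = reps, seed = seed_eval),
    eval_news_fio2 = evaluate_score(scored, "newsfio2_total",
                                    thresholds = thresholds, reps = reps,
                                    seed = seed_eval),
    scored = scored,
    exclusions = test$exclusions
  )
}
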
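test_that("AUROC matches hand-enumerable cases and handles ties", {
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  # positives {2, 3} vs negatives {1, 2}: pairs 1 + 0.5 + 1 + 1 out of 4
  expect_equal(auroc(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE)), 0.875)
  expect_equal(auroc(c(5, 5), c(TRUE, FALSE)), 0.5)
  expect_error(auroc(1:4, rep(TRUE, 4)), class = "newsfio2_undefined_metric")
})

test_that("AUROC equals the all-pairs oracle on random instances", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    s <- sample(0:15, n, replace = TRUE)  # heavy ties, like integer EWS totals
    l <- runif(n) < 0.3
    if (length(unique(l)) < 2) next
    expect_equal(auroc(s, l), oracle_auroc(s, l), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly increasing score transforms", {
  set.seed(32)
  s <- rnorm(300)
  l <- runif(300) < plogis(s)
  a <- auroc(s, l)
  expect_equal(auroc(exp(s), l), a, tolerance = 1e-12)
  expect_equal(auroc(rank(s), l), a, tolerance = 1e-12)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  s <- sample(0:12, 400, replace = TRUE)
  l <- runif(400) < 0.2
  expect_equal(auroc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("bootstrap CI is deterministic under a seed and leaves the RNG alone", {
  set.seed(34)
  s <- rnorm(500) + runif(500)
  l <- runif(500) < 0.2
  set.seed(99); before <- runif(1)
  set.seed(99)
  ci1 <- bootstrap_auroc_ci(s, l, reps = 50, seed = 7)
  after <- runif(1)
  expect_equal(before, after)  # caller's stream untouched
  ci2 <- bootstrap_auroc_ci(s, l, reps = 50, seed = 7)
  expect_equal(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$auroc + 1e-9)
  expect_gte(ci1$ci_high, ci1$auroc - 1e-9)
})

test_that("bootstrap CI collapses to (1, 1) on perfectly separated data", {
  s <- c(rep(1, 50), rep(2, 5))
  l <- c(rep(FALSE, 50), rep(TRUE, 5))
  ci <- bootstrap_auroc_ci(s, l, reps = 20, seed = 1)
  expect_equal(ci$ci_low, 1.0)
  expect_equal(ci$ci_high, 1.0)
})

test_that("operating points reproduce a hand 2x2 table", {
  # TP 8, FN 2, FP 40, TN 50 at threshold 5
  s <- c(rep(5, 8), rep(4, 2), rep(6, 40), rep(1, 50))
  l <- c(rep(TRUE, 10), rep(FALSE, 90))
  op <- operating_point(s, l, 5)
  expect_equal(op$sensitivity, 80)
  expect_equal(op$specificity, 100 * 50 / 90)
  expect_equal(op$ppv, 100 * 8 / 48)
  expect_equal(op$efficiency, 48)

  all_in <- operating_point(s, l, 0)
  expect_equal(all_in$sensitivity, 100)
  expect_equal(all_in$specificity, 0)

  expect_warning(none <- operating_point(s, l, 99), "PPV undefined")
  expect_equal(none$sensitivity, 0)
  expect_equal(none$efficiency, 0)
  expect_true(is.na(none$ppv))

  # self-consistency with its own confusion counts
  expect_equal(op$sensitivity, 100 * op$tp / (op$tp + op$fn))
  expect_equal(op$efficiency, 100 * (op$tp + op$fp) / (op$tp + op$fp + op$tn + op$fn))
})

test_that("efficiency curve starts at (1, 1) and matches hand fractions", {
  s <- c(0, 1, 1, 2, 3, 3)
  l <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  ec <- efficiency_curve(s, l)
  expect_equal(ec$obs_fraction[ec$threshold == 0], 1)
  expect_equal(ec$event_fraction[ec$threshold == 0], 1)
  expect_equal(ec$obs_fraction[ec$threshold == 2], 3 / 6)
  expect_equal(ec$event_fraction[ec$threshold == 2], 1 / 2)
  expect_false(is.unsorted(ec$obs_fraction))  # rows descend in threshold

  expect_warning(flat <- efficiency_curve(s, rep(FALSE, 6)), "undefined")
  expect_true(all(is.na(flat$event_fraction)))
})

test_that("precision-recall points match hand enumeration", {
  perfect <- pr_curve(c(1, 1, 9, 9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$precision[perfect$threshold == 9], 1)
  expect_equal(perfect$recall[perfect$threshold == 9], 1)

  s <- c(0, 1, 1, 2, 3, 3)
  l <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  pr <- pr_curve(s, l)
  expect_equal(pr$precision[pr$threshold == 3], 1 / 2)
  expect_equal(pr$recall[pr$threshold == 3], 1 / 2)
  expect_equal(pr$precision[pr$threshold == 1], 2 / 5)
  expect_equal(pr$recall[pr$threshold == 0], 1)

  # random scores: precision hovers at prevalence
  set.seed(36)
  s2 <- runif(20000)
  l2 <- runif(20000) < 0.1
  pr2 <- pr_curve(round(s2, 1), l2)
  mid <- pr2[pr2$recall > 0.3 & pr2$recall < 0.9, ]
  expect_true(all(abs(mid$precision - 0.1) < 0.02))
})

test_that("ROC curve is monotone and consistent with AUROC extremes", {
  set.seed(37)
  s <- sample(0:10, 300, replace = TRUE)
  l <- runif(300) < 0.25
  rc <- roc_curve(s, l)
  expect_false(is.unsorted(rc$fpr))
  expect_false(is.unsorted(rc$tpr))
  expect_equal(rc$tpr[nrow(rc)], 1)
})

test_that("window curve equals standard AUROC at the full window and thins to NA", {
  cohort <- generate_cohort(sim_config(n_admissions = 600, seed = 44))
  el <- filter_eligible(cohort$admissions, cohort$observations)
  lab <- tag_events(estimate_fio2(el$observations), el$admissions)
  sc <- score_news(lab)
  abw <- auroc_by_window(sc, "news_total", windows = c(24, 12, 0))
  expect_equal(abw$auroc[1], auroc(sc$news_total, sc$label))
  expect_true(is.na(abw$auroc[abw$window_h == 0]))
  expect_equal(abw$n_pos[abw$window_h == 0], 0L)
  # drifting vitals: discrimination improves as the event approaches
  expect_gte(abw$auroc[abw$window_h == 12], abw$auroc[abw$window_h == 24] - 0.02)
})

test_that("evaluate_score bundles a coherent report with broom methods", {
  cohort <- generate_cohort(sim_config(n_admissions = 500, seed = 45))
  el <- filter_eligible(cohort$admissions, cohort$observations)
  sc <- score_news(tag_events(estimate_fio2(el$observations), el$admissions))
  rep_ <- evaluate_score(sc, "news_total", reps = 50, seed = 2)
  expect_s3_class(rep_, "ews_evaluation")
  expect_lte(rep_$ci_low, rep_$auroc + 1e-9)
  expect_gte(rep_$ci_high, rep_$auroc - 1e-9)
  expect_equal(nrow(rep_$operating_points), 2)
  expect_equal(rep_$n_observations, nrow(sc))

  expect_equal(nrow(glance(rep_)), 1)
  expect_equal(tidy(rep_)$threshold, c(5, 7))
  expect_s3_class(autoplot(rep_, "roc"), "ggplot")
  expect_s3_class(autoplot(rep_, "pr"), "ggplot")
  expect_s3_class(autoplot(rep_, "efficiency"), "ggplot")
  expect_s3_class(autoplot(rep_, "auroc_window"), "ggplot")
  expect_output(print(rep_), "AUROC")
})
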
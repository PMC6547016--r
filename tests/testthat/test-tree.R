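banded_instance <- function(n, seed, probs = c(0.02, 0.1, 0.3, 0.6),
                            n_distinct = 20) {
  set.seed(seed)
  vals <- sort(runif(n_distinct, 0.21, 1))
  x <- sample(vals, n, replace = TRUE)
  p <- probs[findInterval(x, c(0.22, 0.37, 0.53), left.open = TRUE) + 1]
  tibble::tibble(calculated_fio2 = x, label = runif(n) < p)
}

total_gini_decrease <- function(x, y, cuts) {
  g <- findInterval(x, sort(cuts), left.open = TRUE)
  oracle_gini_mass(y) -
    sum(vapply(0:length(cuts), function(b) oracle_gini_mass(y[g == b]), numeric(1)))
}

test_that("degenerate inputs raise derivation errors", {
  lab <- tibble::tibble(calculated_fio2 = runif(50, 0.21, 1), label = FALSE)
  expect_error(derive_fio2_bands(lab), class = "newsfio2_derivation_error")
  few <- tibble::tibble(calculated_fio2 = rep(c(0.3, 0.5), 25),
                        label = rep(c(TRUE, FALSE), 25))
  expect_error(derive_fio2_bands(few), class = "newsfio2_derivation_error")
})

test_that("the first split equals the exhaustive best single cut", {
  for (s in 1:10) {
    d <- banded_instance(200, seed = s)
    fit <- suppressWarnings(derive_fio2_bands(d))
    oc1 <- oracle_best_cuts(d$calculated_fio2, d$label, k = 1, min_n = 2)
    expect_equal(fit$splits$cut[1], oc1)
  }
})

test_that("greedy cuts attain nearly the exhaustive triple's impurity decrease", {
  ratios <- vapply(1:15, function(s) {
    d <- banded_instance(200, seed = 100 + s)
    fit <- suppressWarnings(derive_fio2_bands(d))
    oc <- oracle_best_cuts(d$calculated_fio2, d$label, k = 3, min_n = 2)
    greedy <- total_gini_decrease(d$calculated_fio2, d$label, fit$cut_points)
    best <- total_gini_decrease(d$calculated_fio2, d$label, oc)
    expect_lte(greedy, best + 1e-9)  # the oracle is the optimum
    greedy / best
  }, numeric(1))
  expect_true(all(ratios >= 0.8))
  expect_gte(median(ratios), 0.99)
})

test_that("planted two-band structure is recovered with a single cut", {
  set.seed(5)
  x <- runif(50000, 0.21, 1)
  y <- runif(50000) < ifelse(x > 0.45, 0.08, 0.01)
  fit <- derive_fio2_bands(tibble::tibble(calculated_fio2 = x, label = y),
                           tree_config(max_cut_points = 1))
  expect_equal(fit$cut_points, 0.45, tolerance = 0.02 / 0.45)
})

test_that("recovered cuts converge toward planted cuts as n grows", {
  planted <- c(0.22, 0.37, 0.53)
  err <- vapply(c(50000, 500000), function(n) {
    d <- generate_banded_fio2_labels(n, sim_config(seed = 77))
    fit <- derive_fio2_bands(d)
    max(abs(fit$cut_points - planted))
  }, numeric(1))
  expect_lt(err[2], 0.02)
  expect_lte(err[2], err[1] + 0.005)
})

test_that("derived cut-points are invariant to duplicating the dataset", {
  d <- banded_instance(300, seed = 12)
  f1 <- suppressWarnings(derive_fio2_bands(d))
  f3 <- suppressWarnings(derive_fio2_bands(dplyr::bind_rows(d, d, d)))
  expect_equal(f1$cut_points, f3$cut_points)
})

test_that("uninformative labels produce a near-zero-gain diagnostic", {
  cfg <- sim_config(band_event_probs = rep(0.05, 4), seed = 3)
  d <- generate_banded_fio2_labels(20000, cfg)
  w <- capture_warnings(fit <- derive_fio2_bands(d))
  expect_true(any(grepl("near-zero impurity gain", w)))
  expect_lt(fit$gain_fraction, 0.01)
})

test_that("the first cut matches an independent recursive partitioner", {
  skip_if_not_installed("rpart")
  d <- banded_instance(5000, seed = 8)
  fit <- derive_fio2_bands(d)
  rp <- rpart::rpart(label ~ calculated_fio2, data = d, method = "class",
                     parms = list(split = "gini"),
                     control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                    minbucket = 50))
  rp_cut <- rp$splits[1, "index"]
  expect_equal(fit$splits$cut[1], unname(rp_cut), tolerance = 1e-8)
})

test_that("band tallies conserve observations and events", {
  d <- banded_instance(500, seed = 21)
  rep_ <- band_report(d)
  expect_equal(sum(rep_$n_obs), nrow(d))
  expect_equal(sum(rep_$n_events), sum(d$label))
  expect_equal(sum(rep_$pct_obs), 100)

  empty <- band_report(d[0, ])
  expect_equal(empty$n_obs, rep(0L, 4))
  expect_equal(empty$n_events, rep(0L, 4))
})

test_that("hand-built observations tally into the expected bands", {
  d <- tibble::tibble(
    calculated_fio2 = c(0.21, 0.215, 0.25, 0.30, 0.37, 0.40, 0.50, 0.55, 0.80, 1.0),
    label = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
  rep_ <- band_report(d)
  expect_equal(rep_$n_obs, c(2L, 3L, 2L, 3L))
  expect_equal(rep_$n_events, c(0L, 1L, 1L, 2L))
})

test_that("tidy and glance summarise a band fit", {
  d <- generate_banded_fio2_labels(30000, sim_config(seed = 14))
  fit <- derive_fio2_bands(d)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$n_obs), nrow(d))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$monotone_event_rate)
  expect_s3_class(fit$bands, "fio2_bands")
})
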
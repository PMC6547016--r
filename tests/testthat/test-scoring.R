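test_that("NEWS scores the oxygen item binarily and vitals by chart bands", {
  normal <- make_obs()
  expect_equal(score_news(normal)$news_total, 0L)

  on_o2 <- make_obs(device = "nasal_cannula", o2_flow_lpm = 2)
  s <- score_news(on_o2)
  expect_equal(s$score_oxygen, 2)
  expect_equal(s$news_total, 2L)

  tachypnoea <- make_obs(rr = 26)
  expect_equal(score_news(tachypnoea)$news_total, 3L)

  # hand-scored mixed case against the published chart: rr 22 (2), spo2 93
  # (2), temp 35.5 (1), sbp 95 (2), hr 115 (2), V (3), oxygen (2)
  sick <- make_obs(rr = 22, spo2 = 93, temp = 35.5, sbp = 95, hr = 115,
                   avpu = "V", device = "simple_mask", o2_flow_lpm = 6)
  expect_equal(score_news(sick)$news_total, 14L)
})

test_that("band assignment honours the published one-decimal percent edges", {
  b <- fio2_bands()
  expect_equal(assign_band(c(0.21, 0.22, 0.221, 0.37, 0.371, 0.53, 0.531, 1.0), b),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(assign_band(0.15, b), class = "newsfio2_domain_error")
  expect_error(assign_band(1.2, b), class = "newsfio2_domain_error")
  expect_error(fio2_bands(c(0.5, 0.4, 0.6)), class = "newsfio2_input_error")
})

test_that("the graded oxygen item replaces the binary one", {
  base <- make_obs(device = "simple_mask", o2_flow_lpm = 5)

  mid <- score_news_fio2(dplyr::mutate(base, calculated_fio2 = 0.45))
  expect_equal(mid$score_fio2, 2)  # weight-2 band is NEWS-equivalent
  expect_equal(mid$newsfio2_total, score_news(base)$news_total)

  high <- score_news_fio2(dplyr::mutate(base, calculated_fio2 = 0.60))
  expect_equal(high$score_fio2, 3)
  expect_equal(high$newsfio2_total, score_news(base)$news_total + 1L)

  dilute <- score_news_fio2(dplyr::mutate(base, calculated_fio2 = 0.215))
  expect_equal(dilute$score_fio2, 0)
})

test_that("NEWS-FiO2 is monotone in FiO2 while NEWS is flat on oxygen", {
  fio2 <- seq(0.21, 1, by = 0.01)
  obs <- make_obs(n = length(fio2), device = "simple_mask", o2_flow_lpm = 5)
  obs$calculated_fio2 <- fio2
  graded <- score_news_fio2(obs)$newsfio2_total
  expect_false(is.unsorted(graded))
  expect_equal(length(unique(score_news(obs)$news_total)), 1)
  expect_true(max(graded) > min(graded))
})

test_that("total equals the sum of sub-scores and respects structural maxima", {
  set.seed(20)
  n <- 400
  obs <- make_obs(n = n,
                  hr = runif(n, 30, 180), rr = runif(n, 6, 40),
                  sbp = runif(n, 60, 240), spo2 = runif(n, 70, 100),
                  temp = runif(n, 34, 41),
                  avpu = sample(c("A", "V", "P", "U"), n, replace = TRUE),
                  device = sample(c("room_air", "nasal_cannula"), n, replace = TRUE))
  obs$o2_flow_lpm <- ifelse(obs$device == "room_air", NA_real_, 2)
  obs$calculated_fio2 <- runif(n, 0.21, 1)
  news <- score_news(obs)
  grad <- score_news_fio2(obs)
  sub_cols <- c("score_rr", "score_spo2", "score_temp", "score_sbp",
                "score_hr", "score_consciousness")
  expect_equal(news$news_total,
               as.integer(rowSums(news[, c(sub_cols, "score_oxygen")])))
  expect_equal(grad$newsfio2_total,
               as.integer(rowSums(grad[, c(sub_cols, "score_fio2")])))
  expect_true(all(news$news_total >= 0 & news$news_total <= 20))
  expect_true(all(grad$newsfio2_total >= 0 & grad$newsfio2_total <= 21))

  # variant difference is exactly the oxygen-item swap
  both <- score_news_fio2(news)
  expect_equal(both$newsfio2_total - both$news_total,
               as.integer(both$score_fio2 - both$score_oxygen))
})

test_that("consciousness can be scored from GCS when AVPU is absent", {
  gcs_only <- make_obs(avpu = NA_character_, gcs = 3L)
  expect_equal(score_news(gcs_only)$score_consciousness, 3)
  expect_equal(score_news(make_obs(avpu = NA_character_, gcs = 15L))$score_consciousness, 0)
  expect_error(score_news(make_obs(avpu = NA_character_, gcs = NA_integer_)),
               class = "newsfio2_input_error")
})

test_that("incomplete observation sets are refused by the scorers", {
  expect_error(score_news(make_obs(temp = NA_real_)),
               class = "newsfio2_input_error")
  expect_error(score_news_fio2(make_obs()), class = "newsfio2_input_error")
})

test_that("charts and bands round-trip through YAML configuration", {
  chart <- news_chart(oxygen_supplemental_weight = 2)
  p1 <- withr::local_tempfile(fileext = ".yaml")
  write_news_chart(chart, p1)
  chart2 <- read_news_chart(p1)
  expect_equal(unclass(chart2), unclass(chart), tolerance = 1e-12)

  bands <- fio2_bands(c(0.25, 0.4, 0.6))
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_fio2_bands(bands, p2)
  expect_equal(read_fio2_bands(p2)$cut_points, bands$cut_points)
})
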
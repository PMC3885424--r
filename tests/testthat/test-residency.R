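rel <- UTC("2010-08-16 00:00:00")

test_that("monitoring window takes the earlier of battery and array service", {
  recs <- make_recs(rel, days = 1448)
  w <- monitoring_window(make_tag(battery_days = 696L, delay = c(50, 130)),
                         recs)
  expect_equal(w$potential_days, 696L)

  recs432 <- make_recs(rel, days = 432)
  w2 <- monitoring_window(make_tag(battery_days = 1448L), recs432)
  expect_equal(w2$potential_days, 432L)

  # release on the retrieval day: floor of one day
  recs0 <- make_recs(rel, days = 1448)
  tag0 <- make_tag(release = recs0$deployed_to[1])
  expect_error(monitoring_window(tag0, recs0), "no overlap")
  tag1 <- make_tag(release = recs0$deployed_to[1] - 3600)
  expect_equal(monitoring_window(tag1, recs0)$potential_days, 1L)
})

test_that("residency index is detected days over potential days", {
  recs <- make_recs(rel, days = 432)
  w <- monitoring_window(make_tag(), recs)
  expect_equal(residency_index(daily_from_offsets(integer(0)), w), 0)
  expect_equal(residency_index(daily_from_offsets(0:431), w), 1)
  # 155 detected days of a 432-day window
  expect_equal(residency_index(daily_from_offsets(seq_len(155) - 1, rel), w),
               155 / 432, tolerance = 1e-12)
  expect_equal(round(155 / 432, 4), 0.3588)
})

test_that("adding a detected day never lowers the residency index", {
  recs <- make_recs(rel, days = 432)
  w <- monitoring_window(make_tag(), recs)
  set.seed(1)
  for (rep in 1:20) {
    days <- sort(sample(0:431, sample(1:100, 1)))
    extra <- sample(setdiff(0:431, days), 1)
    expect_gte(residency_index(daily_from_offsets(c(days, extra), rel), w),
               residency_index(daily_from_offsets(days, rel), w))
  }
})

test_that("the four occurrence categories classify their worked examples", {
  recs <- make_recs(rel, days = 432)
  w <- monitoring_window(make_tag(), recs)

  # year-round presence: 183 detected days alternating over the window
  resident_days <- seq(0, 364, by = 2)
  expect_equal(length(resident_days), 183)
  daily <- daily_from_offsets(resident_days, rel)
  ri <- residency_index(daily, w)
  expect_gt(ri, 0.30)
  expect_equal(classify_behaviour(daily, w, ri), "resident")

  # detection at release then a single re-detection at day 326
  expect_equal(classify_behaviour(daily_from_offsets(c(0, 326), rel), w),
               "transient")

  # detections only on days 2-5 post-release
  expect_equal(classify_behaviour(daily_from_offsets(2:5, rel), w),
               "passer_by")

  # no detections at all
  expect_equal(classify_behaviour(daily_from_offsets(integer(0)), w),
               "passer_by")

  # >=5 days in each of >=3 months of a calendar year at low RI
  pr_days <- c(0:7, 31:38, 62:69)  # Aug, Sep, Oct 2010
  daily_pr <- daily_from_offsets(pr_days, rel)
  ri_pr <- residency_index(daily_pr, w)
  expect_lt(ri_pr, 0.30)
  expect_equal(classify_behaviour(daily_pr, w, ri_pr), "pseudo_resident")
})

test_that("classification is total and order-invariant", {
  recs <- make_recs(rel, days = 432)
  tag <- make_tag()
  w <- monitoring_window(tag, recs)
  labels <- c("resident", "pseudo_resident", "transient", "passer_by")
  set.seed(7)
  for (rep in 1:25) {
    days <- sort(sample(0:431, sample(0:200, 1)))
    lab <- classify_behaviour(daily_from_offsets(days, rel), w)
    expect_true(lab %in% labels)
  }
  # degenerate short windows still get exactly one label
  recs_short <- make_recs(rel, days = 20)
  w_short <- monitoring_window(tag, recs_short)
  for (days in list(integer(0), 0L, c(0L, 19L), 0:19))
    expect_true(classify_behaviour(daily_from_offsets(days, rel), w_short)
                %in% labels)

  # permuting raw detection order changes nothing
  times <- rel + c(0, 5, 40, 90, 326) * 86400 + 3600
  det <- det_at(times)
  set.seed(8)
  perm <- det[sample(nrow(det)), ]
  s1 <- residency_summary(det, tag, recs)
  s2 <- residency_summary(perm, tag, recs)
  expect_equal(s1, s2)
})

test_that("detection-day summary computes gaps, counts and labels", {
  recs <- make_recs(rel, days = 432)
  tag <- make_tag()
  det <- det_at(rel + c(0, 10, 20) * 86400 + 7200)
  s <- residency_summary(det, tag, recs)
  expect_equal(s$days_detected, 3L)
  expect_equal(s$mean_gap_days, 10)
  expect_equal(s$n_detections, 3L)

  s1 <- residency_summary(det_at(rel + 7200), tag, recs)
  expect_true(is.na(s1$mean_gap_days))

  s0 <- residency_summary(det_at(rel[0]), tag, recs)
  expect_equal(s0$days_detected, 0L)
  expect_equal(s0$behaviour, "passer_by")
})

test_that("simulated residents report days-detected equal to the truth sidecar", {
  for (s in 1:5) {
    sim <- simulate_telemetry(sim_config(seed = s, duration_days = 40,
                                         regime = "resident"))
    win <- monitoring_window(sim$tags, sim$receivers)
    daily <- daily_detections(sim$detections, sim$receivers, win)
    em <- attr(sim$detections, "emissions")
    truth_days <- unique(as.Date(em$time[!is.na(em$receiver_id)], tz = "UTC"))
    expect_setequal(as.character(unique(daily$day)), as.character(truth_days))
  }
})
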
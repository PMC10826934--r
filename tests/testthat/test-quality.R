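test_that("participation days count distinct local dates with data", {
  w <- test_window()
  # one point on each of 7 local days
  p7 <- make_points((0:6) * 86400 + 3600, lon = 0, lat = 35.9)
  expect_equal(participation_days(p7, w), 7L)
  # all points on one date
  p1 <- make_points(c(3600, 7200, 10800), lon = 0, lat = 35.9)
  expect_equal(participation_days(p1, w), 1L)
  expect_equal(participation_days(p1[0, ], w), 0L)
  # dropout days reduce the count by the generator's schedule
  cfg <- test_cohort_config(n_urban = 1, n_non_urban = 0, days = 7,
                            dropout = 0.45, seed = 21,
                            artifact_rates = no_artifacts)
  coh <- simulate_cohort(cfg)
  tr <- coh$points
  active_days <- length(unique(
    format(tr$timestamp, "%Y-%m-%d", tz = coh$window$timezone)))
  expect_equal(participation_days(tr, coh$window), active_days)
  expect_lte(active_days, 7L)
})

test_that("temporal coverage is the fraction of covered whole minutes", {
  w <- test_window()
  # full coverage of exactly one of seven days: 1440/10080
  p <- make_points(seq(0, 86400 - 60, by = 60) + 1, lon = 0, lat = 35.9)
  expect_equal(temporal_coverage(p, w), 1440 / 10080)
  expect_equal(temporal_coverage(p[0, ], w), 0)
  # every minute covered -> 1
  w1 <- test_window(days = 1)
  pf <- make_points(seq(0, 86400 - 60, by = 60) + 30, lon = 0, lat = 35.9,
                    window = w1)
  expect_equal(temporal_coverage(pf, w1), 1)
})

test_that("participant summary reports gap/accuracy stats and flags", {
  w <- test_window()
  p <- make_points(c(0, 60, 120), lon = c(0, 1, 2) * 1e-4, lat = 35.9,
                   accuracy = 5)
  q <- participant_quality_summary(p, w)
  expect_equal(q$time_gap_mean, 60)
  expect_equal(q$time_gap_median, 60)
  expect_equal(q$time_gap_sd, 0)
  expect_equal(q$accuracy_mean, 5)
  expect_equal(q$accuracy_sd, 0)
  expect_equal(q$n_points, 3)
  # < 2 points: stats undefined (NA, never zero), counts still reported
  q1 <- participant_quality_summary(p[1, ], w)
  expect_true(is.na(q1$time_gap_mean))
  expect_true(is.na(q1$distance_gap_median))
  expect_equal(q1$n_points, 1)
  expect_equal(q1$n_days_participated, 1L)
})

test_that("device-conditional cadence shows up in participant medians", {
  cfg <- cohort_config(
    n_urban = 4, n_non_urban = 2, days = 1,
    ios_fraction = c(urban = 0.5, non_urban = 0.5),
    sampling = list(ios = c(meanlog = log(4), sdlog = 0.5),
                    android = c(meanlog = log(30), sdlog = 0.5)),
    artifact_rates = no_artifacts, dropout = 0, seed = 31)
  coh <- simulate_cohort(cfg)
  q <- cohort_quality(coh$points, coh$window)
  m <- merge(q, coh$metas, by = "participant_id")
  med_ios <- median(m$time_gap_median[m$device_os == "ios"])
  med_android <- median(m$time_gap_median[m$device_os == "android"])
  expect_lt(med_ios, med_android)
  # medians recover the configured cadence within 10%
  expect_lt(abs(med_ios - 4) / 4, 0.1)
  expect_lt(abs(med_android - 30) / 30, 0.1)
})

test_that("group summary aggregates participant-level statistics", {
  w <- test_window()
  q <- rbind(
    cbind(participant_quality_summary(
      make_points(c(0, 60), 0, 35.9, pid = "A"), w)),
    cbind(participant_quality_summary(
      make_points(c(0, 120), 0, 35.9, pid = "B"), w)))
  q$temporal_coverage <- c(0.4, 0.6)
  metas <- data.frame(participant_id = c("A", "B"), ruca_code = c(1, 5),
                      residence_setting = c("urban", "non_urban"),
                      device_os = c("ios", "android"),
                      stringsAsFactors = FALSE)
  gs <- group_summary(q, metas, "residence")
  # single-participant group: group mean equals the participant's value
  urban_tg <- gs[gs$group == "urban" & gs$metric == "time_gap_mean", ]
  expect_equal(urban_tg$mean, 60)
  expect_equal(urban_tg$n_participants, 1)
  expect_equal(urban_tg$pct_ios, 100)
  # two-participant pooled view
  gd <- group_summary(q, metas, "device")
  expect_equal(sort(unique(gd$group)), c("android", "ios"))
  both <- group_summary(q, data.frame(
    participant_id = c("A", "B"), ruca_code = c(1, 2),
    residence_setting = c("urban", "urban"),
    device_os = c("ios", "ios"), stringsAsFactors = FALSE), "residence")
  cov_row <- both[both$metric == "temporal_coverage", ]
  expect_equal(cov_row$mean, 0.5)
  expect_equal(cov_row$median, 0.5)
})

test_that("cohort design counts flow through to group summaries", {
  cfg <- test_cohort_config(n_urban = 6, n_non_urban = 2, days = 1,
                            seed = 17, artifact_rates = no_artifacts)
  coh <- simulate_cohort(cfg)
  cl <- clean_trajectories(coh$points, coh$window)
  q <- cohort_quality(cl$points, coh$window)
  gs <- group_summary(q, coh$metas, "residence")
  expect_equal(unique(gs$n_participants[gs$group == "urban"]), 6)
  expect_equal(unique(gs$n_participants[gs$group == "non_urban"]), 2)
})

test_that("outlier incidence reports point-level shares per cell", {
  w <- test_window()
  layer <- list(list(polygon = rect_polygon_t(-79.1, 35.5, -78.5, 36.2),
                     label = "urban"))
  # 100 points at 30 s cadence, one 2-hour silence inserted
  t <- c(seq(0, 30 * 49, by = 30), seq(30 * 49 + 7200, by = 30,
                                       length.out = 50))
  p <- make_points(t, lon = -78.9, lat = 35.9, accuracy = 5)
  metas <- data.frame(participant_id = "P1", ruca_code = 1,
                      residence_setting = "urban", device_os = "ios",
                      stringsAsFactors = FALSE)
  inc <- outlier_incidence(p, metas, layer)
  expect_equal(nrow(inc), 1)
  expect_equal(inc$n_points, 100)
  # 1 of 99 gaps exceeds one hour
  expect_equal(inc$pct_time_gap_outlier, 100 / 99)
  expect_equal(inc$pct_distance_gap_outlier, 0)
  expect_equal(inc$pct_accuracy_outlier, 0)
  expect_equal(inc$pct_points_in_location, 100)
})

test_that("% of points by location sums to 100 within each stratum", {
  cfg <- test_cohort_config(seed = 23)
  coh <- simulate_cohort(cfg)
  cl <- clean_trajectories(coh$points, coh$window)
  inc <- outlier_incidence(cl$points, coh$metas, coh$setting_layer)
  sums <- tapply(inc$pct_points_in_location, inc$residence, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(inc$pct_time_gap_outlier >= 0 &
                    inc$pct_time_gap_outlier <= 100, na.rm = TRUE))
  # right-skewed gaps: medians do not exceed means
  expect_true(all(inc$time_gap_median <= inc$time_gap_mean + 1e-12))
  # per-device stratification yields device-labeled rows
  inc_dev <- outlier_incidence(cl$points, coh$metas, coh$setting_layer,
                               stratify_by_device = TRUE)
  expect_true("device" %in% names(inc_dev))
  sums_dev <- tapply(inc_dev$pct_points_in_location,
                     paste(inc_dev$residence, inc_dev$device), sum)
  expect_true(all(abs(sums_dev - 100) < 1e-9))
})

test_that("participant-level and pooled point-level summaries differ", {
  # two participants with very different cadences: the participant-level
  # mean of means weighs them equally; pooled point-level statistics are
  # dominated by the denser device
  w <- test_window()
  pa <- make_points(seq(0, 3600, by = 2), 0, 35.9, pid = "A")
  pb <- make_points(seq(0, 3600, by = 120), 0, 35.9, pid = "B")
  pts <- rbind(pa, pb)
  q <- cohort_quality(pts, w)
  participant_level_mean <- mean(q$time_gap_mean)       # (2+120)/2 = 61
  pooled <- consecutive_gaps(normalize_trajectory(pts))
  pooled_mean <- mean(pooled$time_gap)                  # ~ 3.9
  expect_equal(participant_level_mean, 61)
  expect_lt(pooled_mean, 10)
})
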
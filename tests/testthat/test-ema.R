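test_that("EMA records match GPS fixes in the same whole minute", {
  w <- test_window()
  p <- make_points(c(5 * 3600 + 312, 5 * 3600 + 480), lon = 0, lat = 35.9)
  ema <- data.frame(participant_id = "P1",
                    timestamp = w$start + 5 * 3600 + 330,  # :30 of :05
                    self_report = "at_home", stringsAsFactors = FALSE)
  res <- match_ema_to_gps(ema, p)
  expect_equal(nrow(res$matched), 1)
  expect_equal(res$n_not_matched, 0L)
  expect_equal(as.numeric(res$matched$gps_timestamp),
               as.numeric(w$start + 5 * 3600 + 312))
  # nearest GPS nearly 3 minutes away: not matched
  ema2 <- data.frame(participant_id = "P1",
                     timestamp = w$start + 5 * 3600 + 650,
                     self_report = "not_home", stringsAsFactors = FALSE)
  res2 <- match_ema_to_gps(ema2, p)
  expect_equal(nrow(res2$matched), 0)
  expect_equal(res2$n_not_matched, 1L)
  # several fixes in the minute: the one nearest the EMA second wins
  p3 <- make_points(5 * 3600 + c(302, 329, 355), lon = c(1, 2, 3) * 1e-4,
                    lat = 35.9)
  res3 <- match_ema_to_gps(ema, p3)
  expect_equal(res3$matched$lon, 2e-4)
})

test_that("GPS-silent EMA minutes surface as the not-matched fraction", {
  cfg <- test_cohort_config(n_urban = 4, n_non_urban = 2, days = 3,
                            seed = 55, artifact_rates = no_artifacts,
                            # sparse cadence: many minutes without a fix
                            sampling = list(
                              ios = c(meanlog = log(150), sdlog = 0.8),
                              android = c(meanlog = log(150), sdlog = 0.8)))
  coh <- simulate_cohort(cfg)
  res <- match_ema_to_gps(coh$ema, coh$points)
  frac <- res$n_not_matched / nrow(coh$ema)
  # with ~150 s mean gaps roughly a third to three quarters of minutes
  # are silent; the matcher must report a commensurate share
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.8)
  expect_equal(nrow(res$matched) + res$n_not_matched, nrow(coh$ema))
})

test_that("column percentages reproduce published contingency columns", {
  # urban 20 m column: 927 vs 107 -> 89.652% / 10.348%
  t1 <- concordance_from_counts(matrix(c(927, 107, 91, 569), 2),
                                buffer = 20, stratum = "urban")
  expect_equal(round(t1$column_pct["at_home", "at_home"], 3), 89.652)
  expect_equal(round(t1$column_pct["not_home", "at_home"], 3), 10.348)
  expect_equal(round(t1$column_pct["not_home", "not_home"], 3), 86.212)
  # non-urban 100 m column: 342 vs 7 -> 97.994% / 2.006%
  t2 <- concordance_from_counts(matrix(c(342, 7, 35, 226), 2),
                                buffer = 100, stratum = "non_urban")
  expect_equal(round(t2$column_pct["at_home", "at_home"], 3), 97.994)
  expect_equal(round(t2$column_pct["not_home", "at_home"], 3), 2.006)
  # columns sum to 100
  expect_equal(colSums(t1$column_pct), c(at_home = 100, not_home = 100))
  # zero column flagged undefined
  t0 <- concordance_from_counts(matrix(c(0, 0, 3, 4), 2), 20, "s")
  expect_true(all(is.na(t0$column_pct[, "at_home"])))
})

test_that("a perfect cohort yields identity concordance", {
  cfg <- test_cohort_config(n_urban = 2, n_non_urban = 1, days = 2,
                            seed = 61, noise_scale = 0, dropout = 0,
                            artifact_rates = no_artifacts)
  coh <- simulate_cohort(cfg)
  cl <- clean_trajectories(coh$points, coh$window)
  tabs <- cohort_concordance(coh$ema, cl$points, coh$homes,
                             buffers = c(20, 50, 100))
  for (t in tabs) {
    expect_equal(t$counts["at_home", "not_home"] +
                   t$counts["not_home", "at_home"], 0)
    expect_equal(unname(t$column_pct["at_home", "at_home"]), 100)
    expect_equal(unname(t$column_pct["not_home", "not_home"]), 100)
  }
})

test_that("agreement summary takes minima and means per buffer", {
  tabs <- reference_concordance_tables()
  agg <- agreement_summary(tabs)
  expect_equal(agg$buffer, c(20, 50, 100))
  # published headline numbers
  expect_equal(round(agg$min_at_home[agg$buffer == 100], 3), 94.157)
  expect_equal(round(min(agg$min_not_home), 3), 83.966)
  # single table: min equals mean
  single <- agreement_summary(tabs[1])
  expect_equal(single$min_at_home, single$mean_at_home)
})

test_that("at-home agreement is non-decreasing in buffer on fixed pairs", {
  # printed reference counts
  tabs <- reference_concordance_tables()
  for (s in c("urban", "non_urban", "android", "ios")) {
    sub <- Filter(function(t) t$stratum == s, tabs)
    ah <- vapply(sub[order(vapply(sub, `[[`, numeric(1), "buffer"))],
                 function(t) t$column_pct["at_home", "at_home"],
                 numeric(1))
    expect_true(all(diff(ah) >= 0))
  }
  # synthetic cohort, same matched set across buffers
  cfg <- test_cohort_config(n_urban = 3, n_non_urban = 2, days = 2,
                            seed = 63, artifact_rates = no_artifacts)
  coh <- simulate_cohort(cfg)
  cl <- clean_trajectories(coh$points, coh$window)
  tabs2 <- cohort_concordance(coh$ema, cl$points, coh$homes,
                              buffers = c(20, 50, 100))
  ah2 <- vapply(tabs2, function(t) t$column_pct["at_home", "at_home"],
                numeric(1))
  expect_true(all(diff(ah2) >= -1e-9))
})

test_that("unmatched counts are attributed to the right stratum", {
  cfg <- test_cohort_config(n_urban = 2, n_non_urban = 2, days = 2,
                            seed = 65, artifact_rates = no_artifacts,
                            sampling = list(
                              ios = c(meanlog = log(120), sdlog = 0.8),
                              android = c(meanlog = log(120), sdlog = 0.8)))
  coh <- simulate_cohort(cfg)
  strata <- setNames(coh$metas$residence_setting,
                     coh$metas$participant_id)
  tabs <- cohort_concordance(coh$ema, coh$points, coh$homes,
                             buffers = 20, strata = strata)
  total_ema <- table(strata[coh$ema$participant_id])
  for (t in tabs) {
    expect_equal(sum(t$counts) + t$n_not_matched,
                 unname(total_ema[t$stratum]))
  }
})
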
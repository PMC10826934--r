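test_that("normalization sorts, dedupes, and keeps the most certain tie", {
  w <- test_window()
  p <- make_points(c(120, 0, 60, 60, 0), lon = c(1, 2, 3, 3.5, 2) / 1000,
                   lat = rep(0.001, 5), accuracy = c(5, 5, 50, 5, 5))
  norm <- normalize_trajectory(p)
  # duplicate (t=0) collapsed; t=60 tie resolved to accuracy 5
  expect_equal(nrow(norm), 3)
  expect_true(all(diff(as.numeric(norm$timestamp)) > 0))
  expect_equal(norm$lon[norm$timestamp == w$start + 60], 3.5 / 1000)
  expect_equal(norm$accuracy, c(5, 5, 5))
})

test_that("study-period filter is half-open [start, end)", {
  w <- test_window()
  p <- make_points(c(-60, 0, 1000, 7 * 86400), lon = 0, lat = 0)
  f <- filter_study_period(p, w)
  expect_equal(nrow(f), 2)
  expect_equal(attr(f, "n_outside_window"), 2L)
  expect_true(w$start %in% f$timestamp)          # start retained
  expect_false((w$start + 7 * 86400) %in% f$timestamp)  # end dropped
})

test_that("haversine matches closed form and an independent oracle", {
  expect_equal(haversine_distance(0, 0, 0, 0), 0)
  # 1 degree of latitude: R * pi / 180
  expect_equal(haversine_distance(0, 0, 0, 1), 6371008.8 * pi / 180,
               tolerance = 1e-9)
  set.seed(7)
  lon1 <- runif(200, -174, 174); lat1 <- runif(200, -85, 85)
  lon2 <- lon1 + runif(200, -3, 3); lat2 <- lat1 + runif(200, -3, 3)
  d <- haversine_distance(lon1, lat1, lon2, lat2)
  oracle <- slc_distance(lon1, lat1, lon2, lat2)
  expect_lt(max(abs(d - oracle) / pmax(oracle, 1)), 1e-6)
})

test_that("consecutive gaps compute time, distance and speed", {
  p <- make_points(c(0, 10), lon = c(0, 0),
                   lat = c(0, 30 / (6371008.8 * pi / 180)))
  g <- consecutive_gaps(p)
  expect_equal(nrow(g), 1)
  expect_equal(g$time_gap, 10)
  expect_equal(g$distance_gap, 30, tolerance = 1e-6)
  expect_equal(g$speed, 3, tolerance = 1e-6)
  # collinear points: distances additive along the path
  p3 <- make_points(c(0, 10, 20), lon = 0, lat = c(0, 1, 2) / 1000)
  g3 <- consecutive_gaps(p3)
  expect_equal(nrow(g3), 2)
  expect_equal(sum(g3$distance_gap),
               haversine_distance(0, 0, 0, 0.002), tolerance = 1e-9)
  # fixed cadence cohort: all gaps equal the cadence
  pc <- make_points(seq(0, 600, by = 60), lon = 0, lat = 0)
  expect_true(all(consecutive_gaps(pc)$time_gap == 60))
  expect_equal(nrow(consecutive_gaps(pc[1, ])), 0)
})

test_that("distance filter handles the degenerate all-equal-gap case", {
  p <- make_points(seq(0, 300, 60), lon = seq(0, 5) / 1000, lat = 0)
  res <- filter_distance_outliers(p)
  expect_equal(res$n_removed, 0L)
  expect_equal(nrow(res$points), 6)
})

test_that("an injected jump costs exactly its own landing point", {
  w <- test_window()
  set.seed(5)
  n <- 1000
  # ~10 m steps east, one 50 km displaced fix in the middle
  lat0 <- 35.9
  step <- 10 / (111320 * cos(lat0 * pi / 180))
  p <- make_points(seq_len(n) * 30, lon = -78.9 + seq_len(n) * step,
                   lat = lat0)
  jump_at <- 500
  xy <- offset_point(p$lon[jump_at], p$lat[jump_at], 45, 50000)
  p$lon[jump_at] <- xy[1]; p$lat[jump_at] <- xy[2]
  res <- filter_distance_outliers(p)
  expect_equal(res$n_removed, 1L)
  expect_equal(nrow(res$points), n - 1)
  # the removed point is the displaced one
  expect_false(xy[1] %in% res$points$lon)
  expect_equal(res$distance_threshold, 3 * res$distance_sd)
})

test_that("speed filter is strict at the threshold boundary", {
  pair <- make_points(c(0, 1), lon = c(0, 250 / (6371008.8 * pi / 180)),
                      lat = 0)  # ~250 m in 1 s
  v <- consecutive_gaps(pair)$speed
  # a gap exactly at the threshold is retained (strict inequality) ...
  expect_equal(filter_speed_outliers(pair, v_max = v)$n_removed, 0L)
  # ... and removed as soon as the threshold sits below it
  res <- filter_speed_outliers(pair, v_max = v * (1 - 1e-12))
  expect_equal(res$n_removed, 1L)
  expect_equal(nrow(res$points), 1)
  # 300 m in 1 s exceeds the default 250 m/s threshold
  at300 <- make_points(c(0, 1), lon = c(0, 300 / (6371008.8 * pi / 180)),
                       lat = 0)
  expect_equal(filter_speed_outliers(at300)$n_removed, 1L)
})

test_that("cleaning report counts reconcile and order is fixed", {
  cfg <- test_cohort_config(seed = 9)
  coh <- simulate_cohort(cfg)
  cl <- clean_trajectories(coh$points, coh$window)
  r <- cl$report
  expect_equal(r$n_retained,
               r$n_input - r$n_duplicates - r$n_outside_window -
                 r$n_distance_outliers - r$n_speed_outliers)
  expect_equal(r$n_retained, nrow(cl$points))
  expect_equal(r$distance_threshold, r$k_sd * r$distance_sd)
  # surviving points unchanged and still ordered
  expect_true(all(cl$points$point_id %in% coh$points$point_id))
  o <- order(cl$points$participant_id, cl$points$timestamp)
  expect_equal(o, seq_len(nrow(cl$points)))
  merged <- merge(cl$points, coh$points, by = "point_id")
  expect_equal(merged$lon.x, merged$lon.y)
  expect_equal(merged$lat.x, merged$lat.y)
})

test_that("second cleaning pass removes no more than the first", {
  cfg <- test_cohort_config(seed = 13)
  coh <- simulate_cohort(cfg)
  cl1 <- clean_trajectories(coh$points, coh$window)
  cl2 <- clean_trajectories(cl1$points, coh$window)
  first <- cl1$report$n_distance_outliers + cl1$report$n_speed_outliers
  second <- cl2$report$n_distance_outliers + cl2$report$n_speed_outliers
  expect_lte(second, first)
  # frozen threshold from pass one: second pass removes nothing
  cl2f <- clean_trajectories(cl1$points, coh$window,
                             abs_threshold = cl1$report$distance_threshold)
  expect_equal(cl2f$report$n_distance_outliers, 0L)
  expect_equal(cl2f$report$n_speed_outliers, 0L)
})

test_that("absolute threshold override reproduces a fixed-cut reading", {
  w <- test_window()
  p <- make_points(seq(0, 900, 30), lon = seq(0, 30) * 1e-4, lat = 35.9)
  xy <- offset_point(p$lon[15], p$lat[15], 90, 12000)
  p$lon[15] <- xy[1]; p$lat[15] <- xy[2]
  res <- filter_distance_outliers(p, abs_threshold = 9865.762)
  expect_equal(res$distance_threshold, 9865.762)
  expect_equal(res$n_removed, 1L)
})
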
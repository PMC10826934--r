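# Participant-level quality metrics (participation days, temporal
# coverage, gap and accuracy statistics) and their grouped summaries, plus
# point-level outlier incidence stratified by residence and activity-space
# setting. The two summary levels are deliberately distinct: grouped
# participant-level statistics are statistics OF per-participant
# statistics, while outlier incidence pools raw points within each cell.

#' Number of participation days
#'
#' A participation day is a local calendar date within the study window
#' with at least one recorded GPS point.
#'
#' @param trajectory one participant's (cleaned) point table.
#' @param window a [study_window()].
#' @param timezone IANA zone for the local calendar; defaults to the
#'   window's timezone.
#' @return integer count (0 for an empty trajectory).
#' @export
participation_days <- function(trajectory, window,
                               timezone = window$timezone) {
  t <- trajectory$timestamp
  t <- t[t >= window$start & t < window$end]
  if (!length(t)) return(0L)
  length(unique(format(t, "%Y-%m-%d", tz = timezone)))
}

# minute bin index (epoch minutes) of instants
minute_bin <- function(t) floor(as.numeric(t) / 60)

#' Temporal coverage of a trajectory
#'
#' Fraction of whole minutes in the study window that contain at least one
#' GPS point. A participant whose device reported every minute of the
#' window scores 1.
#'
#' @inheritParams participation_days
#' @return fraction in \[0, 1\] (0 for an empty trajectory).
#' @export
temporal_coverage <- function(trajectory, window) {
  t <- trajectory$timestamp
  t <- t[t >= window$start & t < window$end]
  first_bin <- minute_bin(window$start)
  last_bin <- minute_bin(window$end - 0.001)  # end minute is exclusive
  total <- last_bin - first_bin + 1
  if (!length(t)) return(0)
  length(unique(minute_bin(t))) / total
}

stat_triplet <- function(x) {
  if (length(x) < 1L || all(is.na(x))) {
    return(c(mean = NA_real_, sd = NA_real_, median = NA_real_))
  }
  c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
    median = stats::median(x, na.rm = TRUE))
}

#' Participant-level quality summary
#'
#' Mean/SD/median of the participant's consecutive time gaps, distance
#' gaps and point accuracies, together with participation days, temporal
#' coverage and the point count. With fewer than two points the gap
#' statistics are undefined and reported as `NA` (never zero).
#'
#' @inheritParams participation_days
#' @return one-row `data.frame` with columns
#'   `<metric>_{mean,sd,median}` for `time_gap`, `distance_gap`,
#'   `accuracy`, plus `n_days_participated`, `temporal_coverage`,
#'   `n_points`.
#' @export
participant_quality_summary <- function(trajectory, window) {
  gaps <- if (nrow(trajectory) >= 2L) consecutive_gaps(trajectory)
          else empty_gaps()
  tg <- stat_triplet(gaps$time_gap)
  dg <- stat_triplet(gaps$distance_gap)
  ac <- stat_triplet(trajectory$accuracy)
  data.frame(
    participant_id = if (nrow(trajectory)) trajectory$participant_id[1]
                     else NA_character_,
    time_gap_mean = tg[["mean"]], time_gap_sd = tg[["sd"]],
    time_gap_median = tg[["median"]],
    distance_gap_mean = dg[["mean"]], distance_gap_sd = dg[["sd"]],
    distance_gap_median = dg[["median"]],
    accuracy_mean = ac[["mean"]], accuracy_sd = ac[["sd"]],
    accuracy_median = ac[["median"]],
    n_days_participated = participation_days(trajectory, window),
    temporal_coverage = temporal_coverage(trajectory, window),
    n_points = nrow(trajectory),
    stringsAsFactors = FALSE)
}

#' Quality summaries for every participant in a point table
#'
#' @param points cleaned GPS point table (many participants).
#' @param window a [study_window()].
#' @return `data.frame`, one row per participant
#'   (see [participant_quality_summary()]).
#' @export
cohort_quality <- function(points, window) {
  trajs <- split_trajectories(points)
  out <- do.call(rbind, lapply(trajs, participant_quality_summary,
                               window = window))
  rownames(out) <- NULL
  out
}

#' Grouped summary of participant-level quality metrics
#'
#' Statistics (mean, SD, median) of the per-participant metrics within
#' each residence or device group — i.e. statistics of participant-level
#' statistics — plus the group size and percentage of iOS users.
#'
#' @param qualities per-participant table from [cohort_quality()].
#' @param metas participant metadata ([load_participant_meta()]).
#' @param group_by `"residence"` or `"device"`.
#' @return long `data.frame` with columns `group`, `n_participants`,
#'   `pct_ios`, `metric`, `mean`, `sd`, `median`.
#' @export
group_summary <- function(qualities, metas,
                          group_by = c("residence", "device")) {
  group_by <- match.arg(group_by)
  m <- merge(qualities, metas, by = "participant_id")
  m$group <- if (group_by == "residence") m$residence_setting else m$device_os
  metrics <- c("time_gap_mean", "time_gap_sd", "time_gap_median",
               "distance_gap_mean", "distance_gap_sd", "distance_gap_median",
               "accuracy_mean", "accuracy_sd", "accuracy_median",
               "n_days_participated", "temporal_coverage", "n_points")
  groups <- sort(unique(m$group))
  rows <- lapply(groups, function(g) {
    sub <- m[m$group == g, , drop = FALSE]
    if (!nrow(sub)) {
      warning("empty group omitted: ", g, call. = FALSE)
      return(NULL)
    }
    do.call(rbind, lapply(metrics, function(met) {
      st <- stat_triplet(sub[[met]])
      data.frame(group = g, n_participants = nrow(sub),
                 pct_ios = 100 * mean(sub$device_os == "ios"),
                 metric = met, mean = st[["mean"]], sd = st[["sd"]],
                 median = st[["median"]], stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Outlier thresholds for point-level quality metrics
#'
#' Defaults: 1 hour for time gaps, 1 km for distance gaps, 1 km for
#' accuracy.
#'
#' @param time_gap_max seconds. @param distance_gap_max metres.
#' @param accuracy_max metres.
#' @return named list.
#' @export
outlier_thresholds <- function(time_gap_max = 3600, distance_gap_max = 1000,
                               accuracy_max = 1000) {
  stopifnot(time_gap_max > 0, distance_gap_max > 0, accuracy_max > 0)
  list(time_gap_max = time_gap_max, distance_gap_max = distance_gap_max,
       accuracy_max = accuracy_max)
}

#' Point-level outlier incidence by residence and activity-space setting
#'
#' Pools GPS points within each residence-by-point-setting cell (optionally
#' further split by device) and reports point-level mean/SD/median of the
#' time gap, distance gap and accuracy, the percentage of gaps/points
#' exceeding the outlier thresholds, the cell point count, and the
#' percentage of the residence stratum's points falling in the cell. A gap
#' inherits the setting label and timestamp of its later point; the first
#' point of each participant has no incoming gap and contributes only to
#' the accuracy and count columns.
#'
#' @param points cleaned GPS point table.
#' @param metas participant metadata.
#' @param setting_layer labeled polygons ([read_geojson_polygons()]).
#' @param thresholds an [outlier_thresholds()] list.
#' @param stratify_by_device also split each cell by device OS.
#' @return `data.frame`, one row per cell.
#' @export
outlier_incidence <- function(points, metas, setting_layer,
                              thresholds = outlier_thresholds(),
                              stratify_by_device = FALSE) {
  points <- normalize_trajectory(points)
  gaps <- consecutive_gaps(points)
  time_gap <- rep(NA_real_, nrow(points))
  dist_gap <- rep(NA_real_, nrow(points))
  time_gap[gaps$idx_next] <- gaps$time_gap
  dist_gap[gaps$idx_next] <- gaps$distance_gap
  setting <- assign_point_setting(points, setting_layer)
  res <- metas$residence_setting[match(points$participant_id,
                                       metas$participant_id)]
  cells <- data.frame(residence = res, setting = setting,
                      stringsAsFactors = FALSE)
  if (stratify_by_device) cells$device <- points$device_os
  key <- do.call(paste, c(cells, sep = "\r"))
  # denominator for "% points by location": the residence stratum,
  # within device when the per-device tables are requested
  stratum_key <- if (stratify_by_device) paste(res, cells$device) else res
  stratum_n <- table(stratum_key)
  out <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    lab <- cells[idx[1], , drop = FALSE]
    tg <- time_gap[idx]; dg <- dist_gap[idx]; ac <- points$accuracy[idx]
    tg_st <- stat_triplet(tg); dg_st <- stat_triplet(dg)
    ac_st <- stat_triplet(ac)
    n_gap <- sum(!is.na(tg))
    cbind(lab, data.frame(
      time_gap_mean = tg_st[["mean"]], time_gap_sd = tg_st[["sd"]],
      time_gap_median = tg_st[["median"]],
      pct_time_gap_outlier =
        if (n_gap) 100 * sum(tg > thresholds$time_gap_max, na.rm = TRUE) /
          n_gap else NA_real_,
      distance_gap_mean = dg_st[["mean"]], distance_gap_sd = dg_st[["sd"]],
      distance_gap_median = dg_st[["median"]],
      pct_distance_gap_outlier =
        if (n_gap) 100 * sum(dg > thresholds$distance_gap_max,
                             na.rm = TRUE) / n_gap else NA_real_,
      accuracy_mean = ac_st[["mean"]], accuracy_sd = ac_st[["sd"]],
      accuracy_median = ac_st[["median"]],
      pct_accuracy_outlier =
        100 * mean(ac > thresholds$accuracy_max, na.rm = TRUE),
      n_points = length(idx),
      pct_points_in_location =
        100 * length(idx) / stratum_n[[stratum_key[idx[1]]]],
      stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  ord <- do.call(order, out[intersect(c("residence", "device", "setting"),
                                      names(out))])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
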
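# Trajectory cleaning: normalization, study-window restriction, and the
# two artifact filters (pooled 3-SD distance-jump removal, then
# impossible-speed removal at 250 m/s). The pipeline order is fixed:
# window filter -> distance filter -> speed filter, with gaps recomputed
# between the two filter steps.

#' Great-circle (haversine) distance in metres
#'
#' Haversine distance on a sphere of radius 6,371,008.8 m.
#'
#' @param lon1,lat1,lon2,lat2 coordinate vectors (degrees, WGS84).
#' @return distance(s) in metres.
#' @export
haversine_distance <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Normalize a GPS point table
#'
#' Sorts points by participant and timestamp, collapses exact duplicate
#' (timestamp, lon, lat) rows, and resolves remaining same-timestamp ties
#' by keeping the point with the smallest accuracy value (the most certain
#' fix).
#'
#' @param points GPS point table (one participant or many).
#' @return normalized table; within each participant, timestamps are
#'   strictly increasing.
#' @export
normalize_trajectory <- function(points) {
  validate_gps_points(points)
  if (nrow(points) == 0L) return(points)
  o <- order(points$participant_id, points$timestamp, points$accuracy,
             points$lon, points$lat)
  p <- points[o, , drop = FALSE]
  # exact duplicates, then same-timestamp ties: first row (lowest accuracy
  # value after the sort above) wins in both cases
  key <- paste(p$participant_id, as.numeric(p$timestamp))
  p <- p[!duplicated(key), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Restrict points to the study window
#'
#' Keeps points with `window$start <= t < window$end` (half-open).
#'
#' @param points GPS point table.
#' @param window a [study_window()].
#' @return filtered table with attribute `n_outside_window`.
#' @export
filter_study_period <- function(points, window) {
  validate_gps_points(points)
  keep <- points$timestamp >= window$start & points$timestamp < window$end
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_outside_window") <- sum(!keep)
  out
}

#' Gaps between consecutive GPS fixes
#'
#' For each participant, computes the time gap (seconds), distance gap
#' (haversine metres) and implied speed (m/s) between each pair of
#' consecutive points. Participants with fewer than two points contribute
#' no rows.
#'
#' @param points normalized GPS point table.
#' @return `data.frame` with columns `participant_id`, `t_prev`, `t_next`,
#'   `time_gap`, `distance_gap`, `speed`, and `idx_next` (row index of the
#'   later point in `points`).
#' @export
consecutive_gaps <- function(points) {
  validate_gps_points(points)
  n <- nrow(points)
  if (n < 2L) return(empty_gaps())
  same <- points$participant_id[-1] == points$participant_id[-n]
  if (!any(same)) return(empty_gaps())
  i_prev <- which(same)
  i_next <- i_prev + 1L
  time_gap <- as.numeric(points$timestamp[i_next]) -
    as.numeric(points$timestamp[i_prev])
  dist_gap <- haversine_distance(points$lon[i_prev], points$lat[i_prev],
                                 points$lon[i_next], points$lat[i_next])
  data.frame(participant_id = points$participant_id[i_next],
             t_prev = points$timestamp[i_prev],
             t_next = points$timestamp[i_next],
             time_gap = time_gap, distance_gap = dist_gap,
             speed = dist_gap / time_gap,
             idx_next = i_next,
             stringsAsFactors = FALSE)
}

empty_gaps <- function() {
  data.frame(participant_id = character(0),
             t_prev = as.POSIXct(character(0), tz = "UTC"),
             t_next = as.POSIXct(character(0), tz = "UTC"),
             time_gap = numeric(0), distance_gap = numeric(0),
             speed = numeric(0), idx_next = integer(0),
             stringsAsFactors = FALSE)
}

# Single forward pass over offending gaps: mark the LATER point of each
# offending gap for removal, skipping gaps whose earlier point is already
# marked (that gap no longer exists between retained points). Distances are
# never recomputed within a pass. Returns row indices (into `points`) to
# remove.
mark_gap_removals <- function(points, gaps, offending) {
  removed <- logical(nrow(points))
  idx <- gaps$idx_next
  for (g in which(offending)) {
    later <- idx[g]
    earlier <- later - 1L  # valid: gaps link adjacent rows per participant
    if (!removed[earlier]) removed[later] <- TRUE
  }
  which(removed)
}

#' Remove distance-jump outliers (pooled 3-SD rule)
#'
#' Computes the standard deviation of the distance-gap distribution pooled
#' across all participants, sets the removal threshold to
#' `k_sd * SD` (or `abs_threshold` when supplied), and removes the later
#' point of every gap whose distance exceeds the threshold. A gap whose
#' earlier point was already removed in this pass is skipped, so a single
#' displaced fix costs exactly one point. Gaps are not recomputed within
#' the pass.
#'
#' @param points normalized, window-filtered GPS point table.
#' @param k_sd threshold multiplier (default 3).
#' @param abs_threshold optional absolute distance threshold in metres,
#'   overriding `k_sd * SD`.
#' @return list with `points` (filtered), `n_removed`, `distance_sd` and
#'   `distance_threshold`. Degenerate inputs (fewer than two gaps, or zero
#'   SD) are a no-op with a warning/zero removals.
#' @export
filter_distance_outliers <- function(points, k_sd = 3, abs_threshold = NULL) {
  gaps <- consecutive_gaps(points)
  if (nrow(gaps) < 2L) {
    warning("fewer than two gaps: distance filter is a no-op",
            call. = FALSE)
    return(list(points = points, n_removed = 0L, distance_sd = NA_real_,
                distance_threshold = NA_real_))
  }
  sd_gap <- stats::sd(gaps$distance_gap)
  threshold <- if (!is.null(abs_threshold)) abs_threshold else k_sd * sd_gap
  if (is.na(threshold) || threshold <= 0) {
    # all gaps identical (SD 0): nothing can be called an outlier
    return(list(points = points, n_removed = 0L, distance_sd = sd_gap,
                distance_threshold = threshold))
  }
  drop_idx <- mark_gap_removals(points, gaps, gaps$distance_gap > threshold)
  out <- if (length(drop_idx)) points[-drop_idx, , drop = FALSE] else points
  rownames(out) <- NULL
  list(points = out, n_removed = length(drop_idx), distance_sd = sd_gap,
       distance_threshold = threshold)
}

#' Remove impossible-speed outliers
#'
#' Recomputes gaps and removes the later point of every gap whose implied
#' speed strictly exceeds `v_max` (default 250 m/s, the high end of
#' commercial aircraft speed). Same single-pass skip rule as
#' [filter_distance_outliers()].
#'
#' @param points GPS point table (run after the distance filter).
#' @param v_max speed threshold in m/s.
#' @return list with `points` and `n_removed`.
#' @export
filter_speed_outliers <- function(points, v_max = 250) {
  gaps <- consecutive_gaps(points)
  if (nrow(gaps) == 0L) return(list(points = points, n_removed = 0L))
  drop_idx <- mark_gap_removals(points, gaps, gaps$speed > v_max)
  out <- if (length(drop_idx)) points[-drop_idx, , drop = FALSE] else points
  rownames(out) <- NULL
  list(points = out, n_removed = length(drop_idx))
}

#' Full trajectory cleaning pipeline
#'
#' Normalizes, restricts to the study window, removes pooled-SD distance
#' jumps, then removes impossible-speed points (gaps recomputed between the
#' two filter steps).
#'
#' @inheritParams filter_study_period
#' @inheritParams filter_distance_outliers
#' @inheritParams filter_speed_outliers
#' @return list with `points` (cleaned table) and `report`
#'   (a `cleaning_report`).
#' @examples
#' cfg <- cohort_config(n_urban = 2, n_non_urban = 1, seed = 1)
#' coh <- simulate_cohort(cfg)
#' cleaned <- clean_trajectories(coh$points, coh$window)
#' cleaned$report
#' @export
clean_trajectories <- function(points, window, k_sd = 3, v_max = 250,
                               abs_threshold = NULL) {
  n_input <- nrow(points)
  p <- normalize_trajectory(points)
  n_dedup <- n_input - nrow(p)
  p <- filter_study_period(p, window)
  n_outside <- attr(p, "n_outside_window")
  dist_res <- filter_distance_outliers(p, k_sd = k_sd,
                                       abs_threshold = abs_threshold)
  speed_res <- filter_speed_outliers(dist_res$points, v_max = v_max)
  report <- structure(list(
    n_input = n_input,
    n_duplicates = n_dedup,
    n_outside_window = n_outside,
    n_distance_outliers = dist_res$n_removed,
    n_speed_outliers = speed_res$n_removed,
    n_retained = nrow(speed_res$points),
    distance_sd = dist_res$distance_sd,
    distance_threshold = dist_res$distance_threshold,
    k_sd = k_sd, v_max = v_max), class = "cleaning_report")
  list(points = speed_res$points, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("GPS cleaning report\n")
  cat(sprintf("  input points:        %d\n", x$n_input))
  cat(sprintf("  duplicate rows:      %d\n", x$n_duplicates))
  cat(sprintf("  outside window:      %d\n", x$n_outside_window))
  cat(sprintf("  distance outliers:   %d (threshold %.3f m = %g x SD %.3f m)\n",
              x$n_distance_outliers, x$distance_threshold, x$k_sd,
              x$distance_sd))
  cat(sprintf("  speed outliers:      %d (> %g m/s)\n",
              x$n_speed_outliers, x$v_max))
  cat(sprintf("  retained:            %d\n", x$n_retained))
  invisible(x)
}

#' @export
as.data.frame.cleaning_report <- function(x, ...) {
  data.frame(lapply(unclass(x), function(v) if (is.null(v)) NA else v))
}
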
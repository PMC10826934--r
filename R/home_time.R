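# Buffered-footprint home geofencing and wake-time-at-home estimation.
# "Home" at buffer b means: inside the building footprint extended outward
# by b metres (b = 0 is the raw footprint). The wake window defaults to
# 08:00-20:30 local time.

#' Home geometry: building footprint plus metric buffers
#'
#' Builds the nested family of geofences used for at-home classification:
#' the raw footprint (buffer 0) and its outward extensions.
#'
#' @param participant_id id string.
#' @param footprint unclosed two-column `lon`/`lat` matrix (WGS84).
#' @param buffers buffer distances in metres (default 20, 50, 100).
#' @return object of class `home_geometry`: list with `participant_id`,
#'   `footprint` and `buffers` (named list of polygons keyed by distance).
#' @export
home_geometry <- function(participant_id, footprint,
                          buffers = c(20, 50, 100)) {
  polys <- lapply(buffers, function(b) buffer_polygon(footprint, b))
  names(polys) <- as.character(buffers)
  structure(list(participant_id = participant_id, footprint = footprint,
                 buffers = polys), class = "home_geometry")
}

#' @export
print.home_geometry <- function(x, ...) {
  cat("Home geometry for", x$participant_id, "- footprint area",
      round(polygon_area_m2(x$footprint), 1), "m^2, buffers:",
      paste(names(x$buffers), collapse = ", "), "m\n")
  invisible(x)
}

#' Buffer a home footprint outward
#'
#' Thin wrapper over [buffer_polygon()] kept for the home-geofencing
#' vocabulary: `buffer_home(fp, 0)` is the footprint itself.
#'
#' @param footprint unclosed `lon`/`lat` matrix.
#' @param distance_m outward distance in metres.
#' @return buffered polygon matrix.
#' @export
buffer_home <- function(footprint, distance_m) {
  buffer_polygon(footprint, distance_m)
}

# polygon for a requested buffer level (0 = footprint)
home_polygon <- function(home, buffer) {
  if (buffer == 0) return(home$footprint)
  poly <- home$buffers[[as.character(buffer)]]
  if (is.null(poly)) poly <- buffer_polygon(home$footprint, buffer)
  poly
}

#' Classify points as at home at a given buffer
#'
#' @param points frame with `lon`, `lat` columns.
#' @param home a [home_geometry()].
#' @param buffer buffer level in metres (0, or one of the home's buffers).
#' @return logical vector, `TRUE` when the point lies inside the selected
#'   geofence (boundary inclusive).
#' @export
classify_at_home <- function(points, home, buffer = 0) {
  point_in_polygon(points$lon, points$lat, home_polygon(home, buffer))
}

#' Daily wake window
#'
#' @param start_local,end_local local clock times as `"HH:MM"` strings
#'   (defaults 08:00 and 20:30).
#' @return list with `start_min`, `end_min` (minutes after local midnight).
#' @export
wake_window <- function(start_local = "08:00", end_local = "20:30") {
  to_min <- function(s) {
    hm <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    hm[1] * 60 + hm[2]
  }
  s <- to_min(start_local); e <- to_min(end_local)
  if (!(e > s)) stop("wake window must end after it starts", call. = FALSE)
  list(start_min = s, end_min = e)
}

# Label each wake-window minute of the study window for one trajectory:
# "home", "away" or "no_data". Minute labels come from the single point
# nearest the minute midpoint (method = "nearest", default) or a majority
# vote over the minute's points (method = "majority").
wake_minute_labels <- function(trajectory, home, buffer, wake = wake_window(),
                               window, timezone = window$timezone,
                               method = c("nearest", "majority")) {
  method <- match.arg(method)
  t <- trajectory$timestamp
  keep <- t >= window$start & t < window$end
  tr <- trajectory[keep, , drop = FALSE]
  # local-clock minute-of-day of each point's minute bin
  bins <- minute_bin(tr$timestamp)
  all_bins <- seq(minute_bin(window$start),
                  minute_bin(window$end - 0.001))
  bin_start <- as.POSIXct(all_bins * 60, origin = "1970-01-01", tz = "UTC")
  lt <- as.POSIXlt(bin_start, tz = timezone)
  min_of_day <- lt$hour * 60 + lt$min
  is_wake <- min_of_day >= wake$start_min & min_of_day < wake$end_min
  wake_bins <- all_bins[is_wake]
  labels <- rep("no_data", length(wake_bins))
  if (nrow(tr)) {
    at_home <- classify_at_home(tr, home, buffer)
    pos <- match(bins, wake_bins)
    ok <- !is.na(pos)
    if (any(ok)) {
      if (method == "nearest") {
        midpoint_off <- abs(as.numeric(tr$timestamp[ok]) -
                              (bins[ok] * 60 + 30))
        o <- order(pos[ok], midpoint_off)
        sel <- o[!duplicated(pos[ok][o])]
        labels[pos[ok][sel]] <-
          ifelse(at_home[ok][sel], "home", "away")
      } else {
        votes_home <- tapply(at_home[ok], pos[ok], mean)
        labels[as.integer(names(votes_home))] <-
          ifelse(votes_home >= 0.5, "home", "away")
      }
    }
  }
  names(labels) <- wake_bins
  labels
}

#' Proportion of wake time spent at home
#'
#' Labels each wake-window minute of the study window as home, away or
#' no-data (from the point nearest the minute midpoint), then returns
#' home-minutes / (home-minutes + away-minutes). Minutes without data are
#' excluded from the denominator; the proportion is `NA` when no labeled
#' minute exists.
#'
#' @param trajectory one participant's cleaned point table.
#' @param home a [home_geometry()].
#' @param buffer buffer level in metres (0 = raw footprint).
#' @param wake a [wake_window()].
#' @param window a [study_window()].
#' @param timezone local timezone (defaults to the window's).
#' @param method `"nearest"` (default) or `"majority"` minute labeling.
#' @return proportion in \[0, 1\], or `NA` when undefined.
#' @export
wake_time_at_home <- function(trajectory, home, buffer = 0,
                              wake = wake_window(), window,
                              timezone = window$timezone,
                              method = "nearest") {
  labels <- wake_minute_labels(trajectory, home, buffer, wake, window,
                               timezone, method)
  n_home <- sum(labels == "home")
  n_away <- sum(labels == "away")
  if (n_home + n_away == 0L) return(NA_real_)
  n_home / (n_home + n_away)
}

#' Wake-time-at-home proportions for a cohort across buffers
#'
#' @param points cleaned GPS point table.
#' @param homes named list of [home_geometry()] keyed by participant id.
#' @param buffers buffer levels (default 0, 20, 50, 100).
#' @inheritParams wake_time_at_home
#' @return `data.frame` with `participant_id`, `buffer`, `proportion`.
#' @export
cohort_wake_time_at_home <- function(points, homes,
                                     buffers = c(0, 20, 50, 100),
                                     wake = wake_window(), window,
                                     timezone = window$timezone,
                                     method = "nearest") {
  trajs <- split_trajectories(points)
  rows <- list()
  for (pid in names(trajs)) {
    home <- homes[[pid]]
    if (is.null(home)) next
    for (b in buffers) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, buffer = b,
        proportion = wake_time_at_home(trajs[[pid]], home, b, wake,
                                       window, timezone, method),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group mean and 95% confidence interval of proportions
#'
#' Normal-approximation interval `mean +/- 1.96 * sd / sqrt(n)`, clipped to
#' \[0, 1\]. With fewer than two defined proportions the mean is returned
#' and the interval is `NA`.
#'
#' @param proportions numeric vector (NAs dropped).
#' @return named numeric vector `(mean, lower95, upper95, n)`.
#' @export
group_proportion_ci <- function(proportions) {
  p <- proportions[!is.na(proportions)]
  n <- length(p)
  if (n == 0L) return(c(mean = NA_real_, lower95 = NA_real_,
                        upper95 = NA_real_, n = 0))
  m <- mean(p)
  if (n < 2L) {
    return(c(mean = m, lower95 = NA_real_, upper95 = NA_real_, n = n))
  }
  half <- 1.96 * stats::sd(p) / sqrt(n)
  c(mean = m, lower95 = max(0, m - half), upper95 = min(1, m + half), n = n)
}

#' Group intervals for wake-time-at-home by stratum and buffer
#'
#' @param proportions table from [cohort_wake_time_at_home()].
#' @param metas participant metadata.
#' @param group_by `"residence"`, `"device"`, or `"overall"`.
#' @return `data.frame` with `group`, `buffer`, `mean`, `lower95`,
#'   `upper95`, `n`.
#' @export
wake_time_group_ci <- function(proportions, metas,
                               group_by = c("residence", "device",
                                            "overall")) {
  group_by <- match.arg(group_by)
  m <- merge(proportions, metas, by = "participant_id")
  m$group <- switch(group_by,
                    residence = m$residence_setting,
                    device = m$device_os,
                    overall = "all")
  combos <- unique(m[c("group", "buffer")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- m[m$group == combos$group[i] & m$buffer == combos$buffer[i], ]
    ci <- group_proportion_ci(sub$proportion)
    data.frame(group = combos$group[i], buffer = combos$buffer[i],
               mean = ci[["mean"]], lower95 = ci[["lower95"]],
               upper95 = ci[["upper95"]], n = ci[["n"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$buffer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot group wake-time-at-home intervals
#'
#' Simple base-graphics interval plot of the group means and 95% CIs by
#' buffer, one panel row per group.
#'
#' @param ci_table output of [wake_time_group_ci()].
#' @export
plot_wake_time_ci <- function(ci_table) {
  ci_table$labpos <- seq_len(nrow(ci_table))
  graphics::plot(ci_table$mean, ci_table$labpos, xlim = c(0, 1),
                 yaxt = "n", xlab = "Proportion of wake time at home",
                 ylab = "", pch = 19)
  graphics::segments(ci_table$lower95, ci_table$labpos,
                     ci_table$upper95, ci_table$labpos)
  graphics::axis(2, at = ci_table$labpos, las = 1, cex.axis = 0.7,
                 labels = paste0(ci_table$group, " ", ci_table$buffer, "m"))
  invisible(ci_table)
}
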
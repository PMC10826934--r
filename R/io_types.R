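#' gpsactivity: quality control and validation of smartphone GPS
#' activity-space data
#'
#' The package implements the measurement side of activity-space research
#' with passively sensed smartphone locations: trajectory cleaning
#' (study-window restriction, pooled 3-SD distance-jump removal,
#' impossible-speed removal), participant- and point-level quality metrics,
#' buffered building-footprint home geofencing, EMA/GPS concordance tables,
#' wake-time-at-home estimation, and a synthetic cohort generator with
#' ground-truth labels for end-to-end verification.
#'
#' @section Data representation:
#' GPS points live in a plain \code{data.frame} with columns
#' \code{participant_id} (character), \code{timestamp} (\code{POSIXct},
#' stored in UTC), \code{lon}, \code{lat} (WGS84 degrees), \code{accuracy}
#' (metres, 68\% confidence radius) and \code{device_os}
#' (\code{"android"}/\code{"ios"}). A "trajectory" is such a frame restricted
#' to one participant. Polygons are two-column \code{lon}/\code{lat}
#' matrices (unclosed rings). All timestamps are UTC internally; a per-study
#' IANA timezone converts to local clock time for day and wake-window logic.
#'
#' @keywords internal
#' @aliases gpsactivity-package
"_PACKAGE"

GPS_COLUMNS <- c("participant_id", "timestamp", "lon", "lat",
                 "accuracy", "device_os")

#' Define a study observation window
#'
#' @param start start instant (`POSIXct`, or a string parseable as ISO-8601
#'   in `timezone`).
#' @param end end instant; defaults to `start + days` days.
#' @param timezone IANA timezone name used for local-time logic (calendar
#'   days, wake windows). Timestamps themselves are stored in UTC.
#' @param days window span in days when `end` is missing (default 7).
#' @return An object of class `study_window` with elements `start`, `end`
#'   (POSIXct, UTC) and `timezone`.
#' @examples
#' study_window("2021-03-15 00:00:00", timezone = "America/New_York")
#' @export
study_window <- function(start, end = NULL, timezone = "America/New_York",
                         days = 7) {
  start <- as_utc_time(start, timezone)
  if (is.null(end)) {
    end <- start + days * 86400
  } else {
    end <- as_utc_time(end, timezone)
  }
  if (!isTRUE(end > start)) {
    stop("study window must satisfy end > start", call. = FALSE)
  }
  structure(list(start = start, end = end, timezone = timezone),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat("Study window:", format(x$start, tz = x$timezone, usetz = TRUE),
      "to", format(x$end, tz = x$timezone, usetz = TRUE), "\n")
  invisible(x)
}

# Parse POSIXct/character to POSIXct in UTC; character parsed in `tz`.
as_utc_time <- function(x, tz) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = tz,
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  attr(out, "tzone") <- "UTC"
  out
}

#' Classify residence as urban or non-urban from a RUCA code
#'
#' Rural-Urban Commuting Area (RUCA) codes 1-3 are classified urban and
#' 4-10 non-urban.
#'
#' @param ruca_code integer vector with values in 1-10.
#' @return character vector, `"urban"` or `"non_urban"`.
#' @examples
#' classify_residence(c(1, 3, 4, 10))
#' @export
classify_residence <- function(ruca_code) {
  code <- as.integer(ruca_code)
  if (any(is.na(code)) || any(code < 1L | code > 10L)) {
    stop("ruca_code must be an integer in 1-10", call. = FALSE)
  }
  ifelse(code <= 3L, "urban", "non_urban")
}

validate_gps_points <- function(points) {
  missing_cols <- setdiff(GPS_COLUMNS, names(points))
  if (length(missing_cols)) {
    stop("GPS point table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(points)
}

# Row-level validity of parsed GPS fields. Returns a logical keep-vector.
gps_row_valid <- function(timestamp, lon, lat, accuracy) {
  !is.na(timestamp) & !is.na(lon) & !is.na(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90 &
    (is.na(accuracy) | accuracy >= 0)
}

#' Read a GPS point CSV into a trajectory table
#'
#' Reads comma-separated GPS fixes (header row required, ISO-8601
#' timestamps) and returns one table of points covering all participants.
#' Rows whose coordinates or timestamps cannot be parsed, or that violate
#' coordinate bounds, are counted and reported via a warning and the
#' `"rejected"` attribute - never silently dropped.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping the canonical names
#'   `participant_id`, `timestamp`, `lon`, `lat`, `accuracy`, `device_os`
#'   to the file's header names. Defaults to identity.
#' @param timezone timezone in which naive timestamps in the file are
#'   interpreted (timestamps carrying an explicit offset are honored by the
#'   parser). Stored internally as UTC.
#' @return `data.frame` of GPS points ordered by participant and time, with
#'   attributes `rejected` (number of invalid rows) and `participants`
#'   (unique ids). Empty file yields a zero-row frame with a warning.
#' @seealso [write_gps_csv()], [split_trajectories()]
#' @export
load_gps_csv <- function(path, column_map = NULL, timezone = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cmap <- resolve_column_map(names(raw), column_map,
                             required = GPS_COLUMNS)
  if (nrow(raw) == 0L) {
    warning("empty GPS file: ", path, call. = FALSE)
    out <- empty_gps_points()
    attr(out, "rejected") <- 0L
    return(out)
  }
  ts <- parse_iso_time(raw[[cmap[["timestamp"]]]], timezone)
  lon <- suppressWarnings(as.numeric(raw[[cmap[["lon"]]]]))
  lat <- suppressWarnings(as.numeric(raw[[cmap[["lat"]]]]))
  acc <- suppressWarnings(as.numeric(raw[[cmap[["accuracy"]]]]))
  keep <- gps_row_valid(ts, lon, lat, acc)
  n_rejected <- sum(!keep)
  if (n_rejected > 0L) {
    warning(n_rejected, " row(s) rejected (unparseable or out-of-range ",
            "coordinates/timestamps) in ", path, call. = FALSE)
  }
  out <- data.frame(
    participant_id = as.character(raw[[cmap[["participant_id"]]]])[keep],
    timestamp = ts[keep],
    lon = lon[keep], lat = lat[keep], accuracy = acc[keep],
    device_os = tolower(as.character(raw[[cmap[["device_os"]]]]))[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- n_rejected
  attr(out, "participants") <- unique(out$participant_id)
  out
}

empty_gps_points <- function() {
  data.frame(participant_id = character(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             lon = numeric(0), lat = numeric(0), accuracy = numeric(0),
             device_os = character(0), stringsAsFactors = FALSE)
}

resolve_column_map <- function(headers, column_map, required) {
  cmap <- stats::setNames(required, required)
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  missing_cols <- cmap[!(cmap %in% headers)]
  if (length(missing_cols)) {
    stop("required column(s) not found in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cmap
}

parse_iso_time <- function(x, timezone) {
  out <- suppressWarnings(
    as.POSIXct(x, tz = timezone,
               tryFormats = c("%Y-%m-%dT%H:%M:%OS%z", "%Y-%m-%dT%H:%M:%OS",
                              "%Y-%m-%d %H:%M:%OS")))
  attr(out, "tzone") <- "UTC"
  out
}

#' Write GPS points to CSV
#'
#' Inverse of [load_gps_csv()]: timestamps are written as ISO-8601 UTC with
#' millisecond precision, coordinates with enough digits to round-trip.
#'
#' @param points GPS point table.
#' @param path output file.
#' @export
write_gps_csv <- function(points, path) {
  validate_gps_points(points)
  out <- points[GPS_COLUMNS]
  out$timestamp <- format(points$timestamp, "%Y-%m-%dT%H:%M:%OS3",
                          tz = "UTC")
  old <- options(digits = 15); on.exit(options(old))
  utils::write.csv(format(out, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a GPS point table into per-participant trajectories
#'
#' @param points GPS point table.
#' @return named list of per-participant point tables, time-ordered.
#' @export
split_trajectories <- function(points) {
  validate_gps_points(points)
  split(points, points$participant_id)
}

#' Read EMA self-reports from CSV
#'
#' @param path CSV with columns (after `column_map`) `participant_id`,
#'   `timestamp`, `self_report`; `self_report` must be `"at_home"` or
#'   `"not_home"`.
#' @inheritParams load_gps_csv
#' @return `data.frame` with parsed timestamps (UTC).
#' @export
load_ema_csv <- function(path, column_map = NULL, timezone = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("participant_id", "timestamp", "self_report")
  cmap <- resolve_column_map(names(raw), column_map, required = req)
  ts <- parse_iso_time(raw[[cmap[["timestamp"]]]], timezone)
  ans <- as.character(raw[[cmap[["self_report"]]]])
  bad <- is.na(ts) | !(ans %in% c("at_home", "not_home"))
  if (any(bad)) {
    warning(sum(bad), " EMA row(s) rejected in ", path, call. = FALSE)
  }
  data.frame(participant_id = as.character(raw[[cmap[["participant_id"]]]]),
             timestamp = ts, self_report = ans,
             stringsAsFactors = FALSE)[!bad, , drop = FALSE]
}

#' Read participant metadata from CSV
#'
#' Derives `residence_setting` from the RUCA code via
#' [classify_residence()].
#'
#' @param path CSV with columns (after `column_map`) `participant_id`,
#'   `ruca_code`, `device_os`.
#' @inheritParams load_gps_csv
#' @return `data.frame` with `participant_id`, `ruca_code`,
#'   `residence_setting`, `device_os`.
#' @export
load_participant_meta <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "ruca_code", "device_os")
  cmap <- resolve_column_map(names(raw), column_map, required = req)
  ruca <- as.integer(raw[[cmap[["ruca_code"]]]])
  data.frame(participant_id = as.character(raw[[cmap[["participant_id"]]]]),
             ruca_code = ruca,
             residence_setting = classify_residence(ruca),
             device_os = tolower(as.character(raw[[cmap[["device_os"]]]])),
             stringsAsFactors = FALSE)
}

#' Read labeled polygons from a GeoJSON FeatureCollection
#'
#' Each feature must carry a Polygon geometry (WGS84); the exterior ring is
#' kept. Properties are attached to each element.
#'
#' @param path GeoJSON file.
#' @return list of elements, each a list with `polygon` (two-column
#'   `lon`/`lat` matrix, unclosed) and the feature's properties (e.g.
#'   `label`, `participant_id`).
#' @seealso [write_geojson_polygons()]
#' @export
read_geojson_polygons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon geometries are supported", call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(xy) {
      c(lon = as.numeric(xy[[1]]), lat = as.numeric(xy[[2]]))
    }))
    # GeoJSON rings are closed; store unclosed
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    c(list(polygon = m), f$properties)
  })
}

#' Write labeled polygons to a GeoJSON FeatureCollection
#'
#' @param polys list as returned by [read_geojson_polygons()]: each element
#'   has a `polygon` matrix plus arbitrary scalar properties.
#' @param path output file.
#' @export
write_geojson_polygons <- function(polys, path) {
  features <- lapply(polys, function(p) {
    ring <- rbind(p$polygon, p$polygon[1, , drop = FALSE])  # close the ring
    coords <- lapply(seq_len(nrow(ring)),
                     function(i) as.numeric(ring[i, 1:2]))
    props <- p[setdiff(names(p), "polygon")]
    list(type = "Feature",
         properties = if (length(props)) props else stats::setNames(list(), character(0)),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assign urban/non-urban setting labels to GPS points
#'
#' Labels each point with the label of the first setting polygon that
#' contains it (boundary inclusive); points contained by no polygon get
#' `"unknown"`.
#'
#' @param points GPS point table (or any frame with `lon`, `lat`).
#' @param setting_layer list of elements with `polygon` and `label`, as from
#'   [read_geojson_polygons()].
#' @return character vector of labels, one per point.
#' @export
assign_point_setting <- function(points, setting_layer) {
  if (!length(setting_layer)) stop("setting layer is empty", call. = FALSE)
  out <- rep("unknown", nrow(points))
  undecided <- rep(TRUE, nrow(points))
  for (feat in setting_layer) {
    if (!any(undecided)) break
    inside <- point_in_polygon(points$lon[undecided], points$lat[undecided],
                               feat$polygon)
    idx <- which(undecided)[inside]
    out[idx] <- feat$label
    undecided[idx] <- FALSE
  }
  out
}
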
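# EMA/GPS concordance: match self-reports to the GPS fix recorded in the
# same whole minute and cross-tabulate the EMA answer against the
# geofence-derived at-home status at each buffer. Percentages are column
# percentages within GPS status, as in validation-study contingency
# tables; the "at-home diagonal agreement" of a table is the percentage of
# GPS-at-home observations whose EMA answer is also at-home.

#' Match EMA records to GPS fixes at the same timestamp
#'
#' An EMA record matches the GPS point recorded in the same whole minute;
#' when several points share that minute, the one nearest the EMA second
#' is used. Records with no point within `tolerance_s` are counted as not
#' matched.
#'
#' @param ema_records EMA table (`participant_id`, `timestamp`,
#'   `self_report`) for one participant, or many (matching is within
#'   participant).
#' @param points cleaned GPS point table.
#' @param tolerance_s match tolerance in seconds (default 60 = same whole
#'   minute).
#' @return list with `matched` (EMA columns plus the matched point's
#'   `lon`, `lat`, `accuracy`, `device_os`, `gps_timestamp`) and
#'   `n_not_matched`.
#' @export
match_ema_to_gps <- function(ema_records, points, tolerance_s = 60) {
  validate_gps_points(points)
  ekey <- paste(ema_records$participant_id,
                minute_bin(ema_records$timestamp))
  gkey <- paste(points$participant_id, minute_bin(points$timestamp))
  rows <- vector("list", nrow(ema_records))
  n_not_matched <- 0L
  cand_index <- split(seq_len(nrow(points)), gkey)
  for (i in seq_len(nrow(ema_records))) {
    cand <- cand_index[[ekey[i]]]
    # nearest within the minute, and within tolerance of the EMA second
    if (!is.null(cand)) {
      off <- abs(as.numeric(points$timestamp[cand]) -
                   as.numeric(ema_records$timestamp[i]))
      cand <- cand[off <= tolerance_s]
      off <- off[off <= tolerance_s]
    }
    if (is.null(cand) || !length(cand)) {
      n_not_matched <- n_not_matched + 1L
      next
    }
    g <- cand[which.min(off)]
    rows[[i]] <- data.frame(
      participant_id = ema_records$participant_id[i],
      timestamp = ema_records$timestamp[i],
      self_report = ema_records$self_report[i],
      gps_timestamp = points$timestamp[g],
      lon = points$lon[g], lat = points$lat[g],
      accuracy = points$accuracy[g], device_os = points$device_os[g],
      stringsAsFactors = FALSE)
  }
  matched <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(matched)) {
    matched <- data.frame(participant_id = character(0),
                          timestamp = as.POSIXct(character(0), tz = "UTC"),
                          self_report = character(0),
                          gps_timestamp = as.POSIXct(character(0),
                                                     tz = "UTC"),
                          lon = numeric(0), lat = numeric(0),
                          accuracy = numeric(0), device_os = character(0),
                          stringsAsFactors = FALSE)
  }
  rownames(matched) <- NULL
  list(matched = matched, n_not_matched = n_not_matched)
}

LOC_LEVELS <- c("at_home", "not_home")

#' Build a concordance table from a 2x2 count matrix
#'
#' Counts are EMA status (rows: at_home, not_home) by GPS status (columns:
#' at_home, not_home). Column percentages divide each count by its GPS
#' column total; a zero column yields `NA` percentages.
#'
#' @param counts 2x2 numeric matrix (row/column order at_home, not_home).
#' @param buffer buffer level in metres.
#' @param stratum stratum label.
#' @param n_not_matched EMA records without a same-minute GPS fix.
#' @return object of class `concordance_table` with elements `counts`,
#'   `column_pct`, `buffer`, `stratum`, `n_not_matched`.
#' @examples
#' ct <- concordance_from_counts(matrix(c(927, 107, 91, 569), 2),
#'                               buffer = 20, stratum = "urban")
#' ct$column_pct["at_home", "at_home"]  # 89.652
#' @export
concordance_from_counts <- function(counts, buffer, stratum,
                                    n_not_matched = 0L) {
  counts <- matrix(as.numeric(counts), 2, 2,
                   dimnames = list(ema = LOC_LEVELS, gps = LOC_LEVELS))
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  totals <- colSums(counts)
  pct <- sweep(counts, 2, totals, "/") * 100
  pct[, totals == 0] <- NA_real_
  structure(list(counts = counts, column_pct = pct, buffer = buffer,
                 stratum = stratum, n_not_matched = n_not_matched),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, digits = 3, ...) {
  cat(sprintf("EMA x GPS concordance - stratum %s, buffer %sm\n",
              x$stratum, format(x$buffer)))
  disp <- matrix(sprintf("%d (%s%%)", as.integer(x$counts),
                         formatC(x$column_pct, format = "f",
                                 digits = digits)),
                 2, 2, dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  cat("Not matched:", x$n_not_matched, "\n")
  invisible(x)
}

#' Cross-tabulate matched EMA/GPS pairs at a buffer
#'
#' Classifies each matched GPS fix as at-home or not at the requested
#' buffer via the participant's [home_geometry()], and tabulates against
#' the EMA self-report, per stratum.
#'
#' @param matched matched-pair table from [match_ema_to_gps()].
#' @param homes named list of [home_geometry()] keyed by participant id.
#' @param buffer buffer level in metres.
#' @param strata named character vector mapping participant id to stratum
#'   label (e.g. residence or device); a single overall table is produced
#'   when `NULL`.
#' @param n_not_matched optional named count(s) of unmatched EMA records
#'   per stratum (or a scalar for the overall table).
#' @return list of `concordance_table`, one per stratum.
#' @export
concordance_table <- function(matched, homes, buffer, strata = NULL,
                              n_not_matched = NULL) {
  if (is.null(strata)) {
    strata <- stats::setNames(rep("all", length(homes)), names(homes))
  }
  gps_home <- vapply(seq_len(nrow(matched)), function(i) {
    home <- homes[[matched$participant_id[i]]]
    if (is.null(home)) stop("no home geometry for participant ",
                            matched$participant_id[i], call. = FALSE)
    classify_at_home(matched[i, , drop = FALSE], home, buffer)
  }, logical(1))
  gps_status <- ifelse(gps_home, "at_home", "not_home")
  stratum_of <- strata[matched$participant_id]
  lapply(stats::setNames(nm = sort(unique(as.character(strata)))),
         function(s) {
    idx <- which(stratum_of == s)
    counts <- table(factor(matched$self_report[idx], levels = LOC_LEVELS),
                    factor(gps_status[idx], levels = LOC_LEVELS))
    nm <- if (is.null(n_not_matched)) 0L
          else if (length(n_not_matched) == 1L && is.null(names(n_not_matched)))
            as.integer(n_not_matched)
          else as.integer(n_not_matched[[s]])
    concordance_from_counts(unclass(counts), buffer = buffer, stratum = s,
                            n_not_matched = nm)
  })
}

#' Concordance tables across buffers and strata
#'
#' Convenience wrapper running [match_ema_to_gps()] once and
#' [concordance_table()] for every requested buffer, with unmatched EMA
#' counts attributed per stratum.
#'
#' @param ema_records EMA table.
#' @param points cleaned GPS point table.
#' @param homes named list of [home_geometry()].
#' @param buffers buffer levels (default 20, 50, 100).
#' @param strata named character vector participant id -> stratum.
#' @param tolerance_s matching tolerance in seconds.
#' @return flat list of `concordance_table` (one per stratum x buffer).
#' @export
cohort_concordance <- function(ema_records, points, homes,
                               buffers = c(20, 50, 100), strata = NULL,
                               tolerance_s = 60) {
  mres <- match_ema_to_gps(ema_records, points, tolerance_s)
  if (is.null(strata)) {
    strata <- stats::setNames(rep("all", length(homes)), names(homes))
  }
  # unmatched counts per stratum (unit of analysis: EMA observations)
  ema_stratum <- strata[ema_records$participant_id]
  matched_key <- paste(mres$matched$participant_id,
                       as.numeric(mres$matched$timestamp))
  ema_key <- paste(ema_records$participant_id,
                   as.numeric(ema_records$timestamp))
  unmatched <- !(ema_key %in% matched_key)
  nm_by_stratum <- tapply(unmatched, ema_stratum, sum)
  out <- list()
  for (b in buffers) {
    tabs <- concordance_table(mres$matched, homes, b, strata,
                              n_not_matched = nm_by_stratum)
    out <- c(out, tabs)
  }
  out
}

#' Per-buffer agreement summary across concordance tables
#'
#' The at-home (not-home) diagonal agreement of a table is its
#' `column_pct["at_home","at_home"]` (`["not_home","not_home"]`). Reports
#' the minimum and mean of each diagonal across strata, per buffer.
#'
#' @param tables list of `concordance_table`.
#' @return `data.frame` with `buffer`, `min_at_home`, `mean_at_home`,
#'   `min_not_home`, `mean_not_home`.
#' @export
agreement_summary <- function(tables) {
  if (!length(tables)) stop("no concordance tables supplied", call. = FALSE)
  buffers <- vapply(tables, `[[`, numeric(1), "buffer")
  ah <- vapply(tables, function(t) t$column_pct["at_home", "at_home"],
               numeric(1))
  nh <- vapply(tables, function(t) t$column_pct["not_home", "not_home"],
               numeric(1))
  out <- do.call(rbind, lapply(sort(unique(buffers)), function(b) {
    i <- buffers == b
    data.frame(buffer = b,
               min_at_home = min(ah[i], na.rm = TRUE),
               mean_at_home = mean(ah[i], na.rm = TRUE),
               min_not_home = min(nh[i], na.rm = TRUE),
               mean_not_home = mean(nh[i], na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Reference EMA/GPS concordance counts
#'
#' EMA-by-GPS contingency counts from a published seven-day smartphone
#' validation study of urban and non-urban adults (the study whose design
#' this package's defaults emulate), shipped as a plain-text CSV. Useful
#' as reference input for [concordance_from_counts()] and
#' [agreement_summary()].
#'
#' @return `data.frame` with columns `stratum`, `buffer`,
#'   `ema_at_home_gps_at_home`, `ema_not_home_gps_at_home`,
#'   `ema_at_home_gps_not_home`, `ema_not_home_gps_not_home`,
#'   `n_not_matched`.
#' @export
reference_concordance_counts <- function() {
  path <- system.file("extdata", "concordance_reference_counts.csv",
                      package = "gpsactivity", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Concordance tables from the shipped reference counts
#'
#' @return list of `concordance_table`, one per stratum x buffer.
#' @seealso [reference_concordance_counts()]
#' @export
reference_concordance_tables <- function() {
  counts <- reference_concordance_counts()
  lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    concordance_from_counts(
      matrix(c(r$ema_at_home_gps_at_home, r$ema_not_home_gps_at_home,
               r$ema_at_home_gps_not_home, r$ema_not_home_gps_not_home),
             2, 2),
      buffer = r$buffer, stratum = r$stratum,
      n_not_matched = r$n_not_matched)
  })
}
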
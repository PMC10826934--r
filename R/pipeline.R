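# End-to-end orchestration: read (or accept in-memory) inputs, clean,
# compute quality summaries, home-time proportions and EMA concordance,
# and write all report tables as CSV. The R functions are the interface;
# run_pipeline() bundles them for scripted runs.

#' Run the full activity-space QC and validation pipeline
#'
#' Executes the stages in order - load, clean, participant/group quality
#' summaries, outlier incidence, wake-time-at-home intervals, EMA/GPS
#' concordance - and writes every table to `out_dir` along with the
#' cleaning report (JSON) and a run log echoing the parameters. Stages
#' abort with the stage name on failure.
#'
#' @param inputs either a cohort list as returned by [simulate_cohort()],
#'   or a named list of file paths (`gps`, `ema`, `meta`, `homes`,
#'   `setting_layer`) in the formats written by [write_cohort()].
#' @param out_dir output directory (created if needed).
#' @param window a [study_window()]; defaults to the cohort's window when
#'   `inputs` is a cohort.
#' @param k_sd,v_max,abs_threshold cleaning parameters
#'   (see [clean_trajectories()]).
#' @param thresholds an [outlier_thresholds()] list.
#' @param buffers home buffer levels in metres for the wake-time tables.
#' @param concordance_buffers buffer levels for the EMA tables.
#' @param wake a [wake_window()].
#' @param timezone local timezone; defaults to the window's.
#' @return (invisibly) list with `cleaning_report`, `quality`,
#'   `group_residence`, `group_device`, `outlier_incidence`, `wake_time`,
#'   `wake_time_ci`, `concordance`, `agreement`, `files`.
#' @export
run_pipeline <- function(inputs, out_dir, window = NULL, k_sd = 3,
                         v_max = 250, abs_threshold = NULL,
                         thresholds = outlier_thresholds(),
                         buffers = c(0, 20, 50, 100),
                         concordance_buffers = c(20, 50, 100),
                         wake = wake_window(), timezone = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  loaded <- stage("load", {
    if (!is.null(inputs$points)) {
      inputs
    } else {
      homes_raw <- read_geojson_polygons(inputs$homes)
      homes <- lapply(homes_raw, function(h) {
        home_geometry(h$participant_id, h$polygon)
      })
      names(homes) <- vapply(homes_raw, `[[`, character(1),
                             "participant_id")
      list(points = load_gps_csv(inputs$gps),
           ema = load_ema_csv(inputs$ema),
           metas = load_participant_meta(inputs$meta),
           homes = homes,
           setting_layer = read_geojson_polygons(inputs$setting_layer))
    }
  })
  if (is.null(window)) window <- loaded$window
  if (is.null(window)) stop("no study window supplied", call. = FALSE)
  if (is.null(timezone)) timezone <- window$timezone
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cleaned <- stage("clean",
                   clean_trajectories(loaded$points, window, k_sd = k_sd,
                                      v_max = v_max,
                                      abs_threshold = abs_threshold))
  quality <- stage("quality", cohort_quality(cleaned$points, window))
  grp_res <- stage("quality", group_summary(quality, loaded$metas,
                                            "residence"))
  grp_dev <- stage("quality", group_summary(quality, loaded$metas,
                                            "device"))
  incidence <- stage("quality",
                     outlier_incidence(cleaned$points, loaded$metas,
                                       loaded$setting_layer, thresholds))
  wt <- stage("home_time",
              cohort_wake_time_at_home(cleaned$points, loaded$homes,
                                       buffers, wake, window, timezone))
  wt_ci <- stage("home_time", {
    rbind(wake_time_group_ci(wt, loaded$metas, "residence"),
          wake_time_group_ci(wt, loaded$metas, "device"),
          wake_time_group_ci(wt, loaded$metas, "overall"))
  })
  strata_res <- stats::setNames(loaded$metas$residence_setting,
                                loaded$metas$participant_id)
  strata_dev <- stats::setNames(loaded$metas$device_os,
                                loaded$metas$participant_id)
  tables <- stage("ema", {
    c(cohort_concordance(loaded$ema, cleaned$points, loaded$homes,
                         concordance_buffers, strata_res),
      cohort_concordance(loaded$ema, cleaned$points, loaded$homes,
                         concordance_buffers, strata_dev))
  })
  agreement <- stage("ema", agreement_summary(tables))

  files <- c(
    cleaning_report = file.path(out_dir, "cleaning_report.json"),
    quality = file.path(out_dir, "participant_quality.csv"),
    group_residence = file.path(out_dir, "group_summary_residence.csv"),
    group_device = file.path(out_dir, "group_summary_device.csv"),
    outlier_incidence = file.path(out_dir, "outlier_incidence.csv"),
    wake_time = file.path(out_dir, "wake_time_at_home.csv"),
    wake_time_ci = file.path(out_dir, "wake_time_group_ci.csv"),
    concordance = file.path(out_dir, "concordance.csv"),
    agreement = file.path(out_dir, "agreement_summary.csv"),
    run_log = file.path(out_dir, "run_log.txt"))
  stage("write", {
    jsonlite::write_json(unclass(cleaned$report),
                         files[["cleaning_report"]], auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(quality, files[["quality"]], row.names = FALSE)
    utils::write.csv(grp_res, files[["group_residence"]],
                     row.names = FALSE)
    utils::write.csv(grp_dev, files[["group_device"]], row.names = FALSE)
    utils::write.csv(incidence, files[["outlier_incidence"]],
                     row.names = FALSE)
    utils::write.csv(wt, files[["wake_time"]], row.names = FALSE)
    utils::write.csv(wt_ci, files[["wake_time_ci"]], row.names = FALSE)
    utils::write.csv(concordance_long(tables), files[["concordance"]],
                     row.names = FALSE)
    utils::write.csv(agreement, files[["agreement"]], row.names = FALSE)
    writeLines(c(
      paste("gpsactivity", as.character(utils::packageVersion("gpsactivity"))),
      paste("R", paste(R.version$major, R.version$minor, sep = ".")),
      paste("run at:", format(Sys.time(), tz = "UTC", usetz = TRUE)),
      paste("window:", format(window$start, tz = "UTC"), "to",
            format(window$end, tz = "UTC"), window$timezone),
      paste("k_sd:", k_sd), paste("v_max:", v_max),
      paste("buffers:", paste(buffers, collapse = ",")),
      paste("concordance buffers:",
            paste(concordance_buffers, collapse = ","))),
      files[["run_log"]])
  })
  invisible(list(cleaning_report = cleaned$report, quality = quality,
                 group_residence = grp_res, group_device = grp_dev,
                 outlier_incidence = incidence, wake_time = wt,
                 wake_time_ci = wt_ci, concordance = tables,
                 agreement = agreement, files = files))
}

#' Flatten concordance tables to one long data frame
#'
#' @param tables list of `concordance_table`.
#' @return `data.frame` with one row per stratum x buffer x cell.
#' @export
concordance_long <- function(tables) {
  out <- do.call(rbind, lapply(tables, function(t) {
    grid <- expand.grid(ema = LOC_LEVELS, gps = LOC_LEVELS,
                        stringsAsFactors = FALSE)
    data.frame(stratum = t$stratum, buffer = t$buffer,
               ema = grid$ema, gps = grid$gps,
               count = as.vector(t$counts[cbind(grid$ema, grid$gps)]),
               column_pct = as.vector(t$column_pct[cbind(grid$ema,
                                                         grid$gps)]),
               n_not_matched = t$n_not_matched,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
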
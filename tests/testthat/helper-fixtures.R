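# Shared fixture builders. Everything is constructed in code; no binary
# fixtures.

test_tz <- "America/New_York"

test_window <- function(days = 7) {
  study_window("2021-03-15", timezone = test_tz, days = days)
}

# quick GPS point frame; `t` in seconds after the window start
make_points <- function(t, lon, lat, accuracy = 5, pid = "P1",
                        device = "ios", window = test_window()) {
  data.frame(participant_id = pid,
             timestamp = window$start + t,
             lon = unname(lon), lat = unname(lat),
             accuracy = unname(accuracy),
             device_os = device, stringsAsFactors = FALSE,
             row.names = NULL)
}

# small rectangular footprint (half-sizes in metres) centred at lon0/lat0
make_footprint <- function(lon0 = -78.9, lat0 = 35.9, half_w = 6,
                           half_h = 5) {
  m_lon <- 111320 * cos(lat0 * pi / 180)
  cbind(lon = c(lon0 - half_w / m_lon, lon0 + half_w / m_lon,
                lon0 + half_w / m_lon, lon0 - half_w / m_lon),
        lat = c(lat0 - half_h / 111320, lat0 - half_h / 111320,
                lat0 + half_h / 111320, lat0 + half_h / 111320))
}

# a point at a given geodesic offset (metres, bearing degrees) from a base
offset_point <- function(lon, lat, bearing, dist_m) {
  geosphere::destPoint(c(lon, lat), bearing, dist_m, r = 6371008.8)
}

# independent oracle: spherical law of cosines distance
slc_distance <- function(lon1, lat1, lon2, lat2, R = 6371008.8) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dlam <- (lon2 - lon1) * to_rad
  cosarg <- pmin(1, pmax(-1, sin(phi1) * sin(phi2) +
                           cos(phi1) * cos(phi2) * cos(dlam)))
  R * acos(cosarg)
}

# small fast cohort config for tests: coarse cadence, compact trips
test_cohort_config <- function(n_urban = 3, n_non_urban = 2, days = 2,
                               seed = 42,
                               sampling = list(
                                 ios = c(meanlog = log(15), sdlog = 0.6),
                                 android = c(meanlog = log(30),
                                             sdlog = 0.8)),
                               ...) {
  cohort_config(n_urban = n_urban, n_non_urban = n_non_urban, days = days,
                sampling = sampling, seed = seed, ...)
}

no_artifacts <- list(jump_rate = 0, jump_dist_km = c(30, 100),
                     teleport_rate = 0, teleport_dist_m = c(300, 800))

rect_polygon_t <- function(lon_min, lat_min, lon_max, lat_max) {
  cbind(lon = c(lon_min, lon_max, lon_max, lon_min),
        lat = c(lat_min, lat_min, lat_max, lat_max))
}
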
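# Shared fixtures, built in code. Expensive objects (the monsoon scenarios
# and their backward reconstructions) are cached for the whole test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

scenario_1leg <- function() cached("sc1", function() make_monsoon_scenario(seed = 1, leg_count = 1))
scenario_2leg <- function() cached("sc2", function() make_monsoon_scenario(seed = 1, leg_count = 2))

paths_2leg <- function() {
  cached("paths2", function() {
    sc <- scenario_2leg()
    run_multileg_backward(sc$truth$arrival_lon, sc$truth$arrival_lat,
                          sc$truth$expected_arrival_night, sc$field, sc$mask)
  })
}

report_2leg <- function() {
  cached("report2", function() filter_and_count(paths_2leg(), scenario_2leg()$mask))
}

# a tiny uniform field + matching masks for rule checks
tiny_field <- function(u0 = 10, v0 = 0, T0 = 25, extent = c(138, 147, -14, -5),
                       duration_h = 24) {
  make_uniform_field(u0, v0, T0, extent = extent, duration_h = duration_h,
                     res_deg = 1, levels = c(500, 1000, 1500, 2000, 2250))
}

# hand-built backward trajectory for endpoint-validity fixtures
stub_trajectory <- function(end_lon, end_lat, end_time, reason = "dawn_landfall",
                            direction = "backward", leg_index = 1L,
                            duration_h = 9.5, altitude = 1000) {
  end_time <- as.POSIXct(end_time, tz = "UTC")
  pts <- tibble::tibble(
    time = c(end_time + duration_h * 3600, end_time),
    lon = c(end_lon + 3, end_lon), lat = c(end_lat, end_lat),
    altitude_m = altitude, u = 10, v = 0, temperature = 25,
    surface = c("land", "land"))
  structure(list(points = pts, direction = direction, leg_index = leg_index,
                 termination_reason = reason, flight_duration_h = duration_h,
                 release = list(lon = end_lon + 3, lat = end_lat,
                                time = pts$time[1], altitude_m = altitude,
                                direction = direction)),
            class = "trajectory")
}

# wrap stub trajectories into the multileg-paths table shape
stub_paths <- function(trajs) {
  rows <- purrr::map(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    ep <- tr$points[nrow(tr$points), ]
    tibble::tibble(path_id = i, n_legs = 1L,
                   leg1_release_hour = NA_real_, leg1_altitude_m = tr$release$altitude_m,
                   leg2_release_hour = NA_real_, leg2_altitude_m = NA_real_,
                   stopover_lon = NA_real_, stopover_lat = NA_real_,
                   stopover_cell = NA_character_,
                   end_lon = ep$lon, end_lat = ep$lat, end_time = ep$time,
                   termination_reason = tr$termination_reason,
                   legs = list(list(tr)))
  })
  dplyr::bind_rows(rows)
}

gc_km <- function(p1, p2) geosphere::distGeo(p1, p2) / 1000
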
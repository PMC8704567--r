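# Synthetic meteorological fields with controlled structure, plus monsoon
# migration scenarios with known ground truth. Scenario winds are smooth
# (low-order space-time modes on top of a steady jet) so closed-form oracles
# exist for every downstream stage.

.default_levels <- seq(250, 2500, by = 250)

.make_times <- function(start, duration_h, step_h = 1) {
  start <- as.POSIXct(start, tz = "UTC")
  start + seq(0, duration_h * 3600, by = step_h * 3600)
}

.extent_grid <- function(extent, res_deg) {
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4]) {
    stop("`extent` must be c(lon_min, lon_max, lat_min, lat_max) with a non-degenerate box",
         call. = FALSE)
  }
  list(lons = seq(extent[1], extent[2], by = res_deg),
       lats = seq(extent[3], extent[4], by = res_deg))
}

.const_field <- function(times, levels, lats, lons, u0, v0, T0, omega0) {
  dims <- c(length(times), length(levels), length(lats), length(lons))
  met_field(times, levels, lats, lons,
            u = array(u0, dims), v = array(v0, dims),
            temperature = array(T0, dims), omega = array(omega0, dims))
}

#' Uniform synthetic atmosphere
#'
#' Every sample equals `(u0, v0, T0, omega0)`; the workhorse substrate for
#' closed-form checks.
#'
#' @param u0,v0 Wind components (m/s).
#' @param T0 Temperature (degrees C).
#' @param omega0 Vertical pressure velocity (Pa/s).
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param duration_h Field duration (hours), at least 2.
#' @param start First time (UTC).
#' @param res_deg Horizontal grid step (degrees).
#' @param levels Vertical levels (m AGL).
#' @param step_h Time step (hours).
#' @return A [met_field()].
#' @export
make_uniform_field <- function(u0 = 10, v0 = 0, T0 = 25, omega0 = 0,
                               extent = c(115, 150, -15, -5), duration_h = 48,
                               start = "2020-01-14 00:00:00", res_deg = 1,
                               levels = .default_levels, step_h = 1) {
  if (duration_h < 2) stop("`duration_h` must be at least 2", call. = FALSE)
  g <- .extent_grid(extent, res_deg)
  .const_field(.make_times(start, duration_h, step_h), levels, g$lats, g$lons,
               u0, v0, T0, omega0)
}

#' Layered synthetic atmosphere (vertical shear, optional cold cap)
#'
#' Horizontal wind is constant within each level and linearly blended between
#' levels by the interpolator, mimicking the vertical shear of a nocturnal
#' low-level jet. With `cold_above`, temperature drops below the flight gate
#' strictly above that height.
#'
#' @param speed_by_level A data frame with columns `level` (m AGL), `u`, `v`
#'   (m/s); at least two levels.
#' @param cold_above Height (m) above which the air is too cold for flight
#'   (temperature 5 C there, 25 C at and below); `NULL` for uniformly warm.
#' @inheritParams make_uniform_field
#' @return A [met_field()].
#' @export
make_layered_field <- function(speed_by_level, cold_above = NULL,
                               extent = c(115, 150, -15, -5), duration_h = 48,
                               start = "2020-01-14 00:00:00", res_deg = 1,
                               step_h = 1) {
  stopifnot(is.data.frame(speed_by_level), nrow(speed_by_level) >= 2,
            all(c("level", "u", "v") %in% names(speed_by_level)))
  sl <- speed_by_level[order(speed_by_level$level), ]
  g <- .extent_grid(extent, res_deg)
  times <- .make_times(start, duration_h, step_h)
  dims <- c(length(times), nrow(sl), length(g$lats), length(g$lons))
  per_level <- function(vals) {
    aperm(array(rep(vals, each = dims[1]), c(dims[1], dims[2], dims[3], dims[4])),
          c(1, 2, 3, 4))
  }
  temp_lev <- if (is.null(cold_above)) rep(25, nrow(sl)) else ifelse(sl$level > cold_above, 5, 25)
  met_field(times, sl$level, g$lats, g$lons,
            u = per_level(sl$u), v = per_level(sl$v),
            temperature = per_level(temp_lev))
}

#' Synthetic downdraft event field
#'
#' Omega is `peak_omega` inside the event window over a mid-level height band
#' (roughly the 800-950 hPa layer) and exactly zero outside; winds are a weak
#' steady westerly and the air is uniformly warm.
#'
#' @param event_window Length-2 `POSIXct` (UTC): start and end of the
#'   downdraft event, inclusive; must lie within the field span.
#' @param peak_omega Peak vertical pressure velocity (Pa/s, positive =
#'   descending).
#' @param band_m Height band (m AGL) carrying the downdraft.
#' @inheritParams make_uniform_field
#' @return A [met_field()].
#' @export
make_downdraft_field <- function(event_window, peak_omega = 0.5,
                                 extent = c(140, 145, -12, -8), duration_h = 48,
                                 start = "2020-01-17 00:00:00", res_deg = 0.5,
                                 levels = .default_levels, band_m = c(500, 2000),
                                 step_h = 1) {
  times <- .make_times(start, duration_h, step_h)
  ev <- as.POSIXct(event_window, tz = "UTC")
  if (length(ev) != 2 || ev[1] > ev[2] || ev[1] < times[1] || ev[2] > times[length(times)]) {
    stop("`event_window` must be an interval within the field span", call. = FALSE)
  }
  g <- .extent_grid(extent, res_deg)
  fld <- .const_field(times, levels, g$lats, g$lons, 5, 0, 25, 0)
  in_t <- times >= ev[1] & times <= ev[2]
  in_z <- levels >= band_m[1] & levels <= band_m[2]
  fld$omega[in_t, in_z, , ] <- peak_omega
  fld
}

# Smooth seeded perturbation (one space-time mode per component) so repeated
# generation is bit-identical for a given seed.
.perturb <- function(dims, times, lats, lons, seed, amplitude) {
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(seed)
  ph <- stats::runif(6, 0, 2 * pi)
  tn <- (as.numeric(times) - as.numeric(times)[1]) / 86400
  lo <- (lons - lons[1]) / max(diff(range(lons)), 1)
  la <- (lats - lats[1]) / max(diff(range(lats)), 1)
  f_t <- sin(2 * pi * tn + ph[1])
  f_lo <- sin(2 * pi * lo + ph[2])
  f_la <- sin(pi * la + ph[3])
  arr <- outer(outer(outer(f_t, rep(1, dims[2])), f_la), f_lo)
  amplitude * arr
}

#' Monsoon migration scenario with known ground truth
#'
#' Builds a steady monsoon-like jet blowing from a source landmass towards an
#' arrival site, a land/sea mask of circular islands (source, optional
#' stopover, arrival), and the ground truth of the implied forward migration:
#' a moth taking off at dusk from the source crosses the sea on the jet,
#' lands at dawn (on the stopover island for two-leg scenarios, relaunching
#' the next dusk), and reaches the arrival landmass on the expected arrival
#' night. Island positions default to the nominal dawn positions of each
#' night's flight, so the geometry is feasible by construction; explicit
#' geometries are checked against the flight caps.
#'
#' @param seed Integer seed controlling the smooth wind perturbation.
#' @param source_centroid Named or plain `c(lon, lat)`; `NULL` places the
#'   source one nominal night-flight upwind per leg.
#' @param arrival_site `c(lon, lat)` of the arrival point.
#' @param leg_count 1 or 2 flights.
#' @param stopover `c(lon, lat)` of the stopover island (two-leg scenarios);
#'   `NULL` places it at the first night's nominal dawn position.
#' @param jet_speed Jet wind speed (m/s).
#' @param island_radius_km Radius of the source landmass (km). Like the
#'   other islands, kept below one release hour of drift so backward legs
#'   cannot chain an artificial within-island hop.
#' @param arrival_radius_km Radius of the stopover and arrival landmasses
#'   (km). Kept smaller than one release hour of drift so a backward leg
#'   cannot mistake the island it was released over for a take-off site.
#' @param start_date Calendar date of the truth take-off evening.
#' @param params A [flight_params()]; supplies airspeed, windows and caps.
#' @param res_deg Grid resolution (degrees) shared by field and mask.
#' @return A list of class `monsoon_scenario` with elements `field`
#'   ([met_field()]), `mask` ([land_mask()]) and `truth` (one-row tibble:
#'   source, stopover, arrival, take-off time, expected arrival night,
#'   `leg_count`).
#' @export
make_monsoon_scenario <- function(seed = 1, source_centroid = NULL,
                                  arrival_site = c(lon = 142.6, lat = -9.4),
                                  leg_count = 1, stopover = NULL,
                                  jet_speed = 12, island_radius_km = 25,
                                  arrival_radius_km = 35,
                                  start_date = as.Date("2020-01-14"),
                                  params = flight_params(), res_deg = 0.25) {
  stopifnot(leg_count %in% c(1, 2), jet_speed > 0)
  arrival_site <- unname(arrival_site)
  gs <- jet_speed + params$airspeed              # nominal ground speed, m/s
  window_h <- (24 - params$takeoff_local + params$dawn_local) %% 24  # 10 h

  # a night's range under the moving local-solar clock: flying east shortens
  # the night (the clock at the moth's longitude runs ahead of the release
  # clock), so the dusk-to-dawn flight covers window_h / clock_rate hours
  auto_source <- is.null(source_centroid)
  if (auto_source) {
    source_centroid <- unname(geosphere::destPoint(arrival_site, 270,
                                                   leg_count * gs * window_h * 3600))
  } else {
    source_centroid <- unname(as.numeric(source_centroid))
  }
  night_range_m <- function(src) {
    bear <- geosphere::bearing(src, arrival_site)
    lat_mid <- (src[2] + arrival_site[2]) / 2
    dlon_dt <- gs * 3.6 * sin(bear * pi / 180) / (111.195 * cos(lat_mid * pi / 180))
    gs * 3600 * window_h / (1 + dlon_dt / 15)
  }
  d_night <- night_range_m(source_centroid)
  if (auto_source) {
    source_centroid <- unname(geosphere::destPoint(arrival_site, 270, leg_count * d_night))
    d_night <- night_range_m(source_centroid)
  }
  if (leg_count == 2 && is.null(stopover)) {
    bear <- geosphere::bearing(source_centroid, arrival_site)
    stopover <- unname(geosphere::destPoint(source_centroid, bear, d_night))
  }
  waypoints <- if (leg_count == 2) list(source_centroid, as.numeric(stopover), arrival_site)
               else list(source_centroid, arrival_site)
  leg_d <- purrr::map_dbl(seq_len(leg_count), function(i) {
    geosphere::distGeo(waypoints[[i]], waypoints[[i + 1]])
  })
  radii <- c(island_radius_km, rep(arrival_radius_km, length(waypoints) - 1))
  for (li in seq_along(leg_d)) {
    d <- leg_d[li]
    if (d + radii[li + 1] * 1000 < d_night || d > gs * params$oversea_max_h * 3600) {
      stop(sprintf(paste0("scenario-infeasible: leg distance %.0f km cannot be flown at ",
                          "%.1f m/s within the nightly window and the %g h over-sea cap"),
                   d / 1000, gs, params$oversea_max_h), call. = FALSE)
    }
  }

  bear <- geosphere::bearing(source_centroid, arrival_site)
  u0 <- jet_speed * sin(bear * pi / 180)
  v0 <- jet_speed * cos(bear * pi / 180)

  takeoff <- night_window(start_date, source_centroid[1], params)$takeoff_utc
  t_start <- takeoff - 48 * 3600
  duration_h <- 48 + 24 * leg_count + 24
  lon_rng <- range(c(source_centroid[1], arrival_site[1]))
  lat_rng <- range(c(source_centroid[2], arrival_site[2]))
  extent <- c(lon_rng[1] - 6, lon_rng[2] + 2, lat_rng[1] - 2, lat_rng[2] + 2)
  g <- .extent_grid(extent, res_deg)
  times <- .make_times(t_start, duration_h, 1)
  levels <- .default_levels
  dims <- c(length(times), length(levels), length(g$lats), length(g$lons))

  # steady jet + +/-2 % vertical shear + monsoon-onset ramp over the first 6 h
  shear <- 1 + 0.02 * (levels - mean(levels)) / (diff(range(levels)) / 2)
  ramp <- pmin(1, 0.8 + 0.2 * seq_along(times) / 6)
  base <- outer(ramp, shear)                      # time x level
  expand <- function(tl) array(rep(tl, times = dims[3] * dims[4]), dims)
  u <- expand(base * u0) + .perturb(dims, times, g$lats, g$lons, seed, 0.15)
  v <- expand(base * v0) + .perturb(dims, times, g$lats, g$lons, seed + 1000L, 0.15)
  temp_lev <- 25 - 3 * levels / 1000              # warm everywhere aloft
  temperature <- expand(outer(rep(1, dims[1]), temp_lev))
  field <- met_field(times, levels, g$lats, g$lons, u, v, temperature)

  islands <- tibble::tibble(
    lon = purrr::map_dbl(waypoints, 1), lat = purrr::map_dbl(waypoints, 2),
    radius_km = radii,
    host = c(TRUE, rep(FALSE, length(waypoints) - 1)))
  mask <- mask_islands(g$lats, g$lons, islands)

  truth <- tibble::tibble(
    source_lon = source_centroid[1], source_lat = source_centroid[2],
    source_radius_km = island_radius_km,
    stopover_lon = if (leg_count == 2) stopover[1] else NA_real_,
    stopover_lat = if (leg_count == 2) stopover[2] else NA_real_,
    arrival_lon = arrival_site[1], arrival_lat = arrival_site[2],
    takeoff_time = takeoff,
    expected_arrival_night = start_date + (leg_count - 1),
    leg_count = as.integer(leg_count))
  structure(list(field = field, mask = mask, truth = truth, params = params,
                 seed = seed),
            class = "monsoon_scenario")
}

#' @export
print.monsoon_scenario <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("<monsoon_scenario> %d-leg, source (%.2f, %.2f) -> arrival (%.2f, %.2f)\n",
              tr$leg_count, tr$source_lon, tr$source_lat, tr$arrival_lon, tr$arrival_lat))
  cat(sprintf("  take-off %s UTC, expected arrival night %s\n",
              format(tr$takeoff_time, "%Y-%m-%d %H:%M"), tr$expected_arrival_night))
  invisible(x)
}

#' Write a scenario to disk
#'
#' Emits the met field and mask as NetCDF and the ground truth as JSON, so
#' the file-based pipeline entry points can be exercised on synthetic data.
#'
#' @param scenario A `monsoon_scenario`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "monsoon_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(field = file.path(dir, "field.nc"),
             mask = file.path(dir, "mask.nc"),
             truth = file.path(dir, "truth.json"))
  write_met_field(scenario$field, paths[["field"]])
  write_land_mask(scenario$mask, paths[["mask"]])
  truth <- as.list(scenario$truth)
  truth$takeoff_time <- format(scenario$truth$takeoff_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  truth$expected_arrival_night <- format(scenario$truth$expected_arrival_night)
  truth$seed <- scenario$seed
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
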
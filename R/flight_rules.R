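# Nocturnal flight-behaviour rules for wind-borne noctuid migration, kept as
# small pure functions so every behavioural constant is testable in isolation.

#' Flight-behaviour parameters
#'
#' Collects the behavioural constants of the migration model. The defaults
#' encode the standard fall-armyworm parameterisation: downwind flight with a
#' 3.0 m/s self-powered airspeed, dusk take-off around 19:00 local with the
#' nocturnal window running 20:00-05:00, up to 12 h of flight per night over
#' land for at most three consecutive nights, over-sea legs extended until
#' landfall but never beyond 36 h, at most two chained flights through an
#' archipelago, eight candidate flight altitudes between 500 and 2250 m AGL,
#' and a hard low-temperature flight gate at 13.8 degrees C.
#'
#' @param airspeed Self-powered flight speed added along the wind direction
#'   (m/s).
#' @param t_min Minimum air temperature permitting flight (degrees C); the
#'   boundary itself permits flight.
#' @param nightly_max_h Maximum continuous flight per night over land (hours).
#' @param max_nights Maximum consecutive flight nights.
#' @param oversea_max_h Maximum single-flight duration when extended over sea
#'   (hours).
#' @param max_legs Maximum number of chained flights in a stepping-stone
#'   reconstruction.
#' @param takeoff_local Take-off time, local mean solar clock (decimal hours).
#' @param dusk_local,dawn_local Bounds of the nocturnal window, local clock
#'   (decimal hours); dawn belongs to the following morning.
#' @param altitudes_m Candidate launch altitudes (m AGL), strictly increasing.
#' @param step_s Trajectory integration step (seconds).
#' @param takeoff_tolerance_h Half-width of the window around `takeoff_local`
#'   accepted as a valid departure time (hours).
#' @param calm_threshold Wind speed (m/s) below which the downwind heading is
#'   undefined and the self-powered vector is suppressed.
#' @return A `flight_params` list.
#' @export
flight_params <- function(airspeed = 3.0, t_min = 13.8,
                          nightly_max_h = 12, max_nights = 3,
                          oversea_max_h = 36, max_legs = 2,
                          takeoff_local = 19, dusk_local = 20, dawn_local = 5,
                          altitudes_m = c(500, 750, 1000, 1200, 1500, 1750, 2000, 2250),
                          step_s = 300, takeoff_tolerance_h = 1.0,
                          calm_threshold = 0.1) {
  stopifnot(airspeed >= 0, nightly_max_h > 0, nightly_max_h <= oversea_max_h,
            max_legs >= 1, max_nights >= 1, step_s > 0,
            all(diff(altitudes_m) > 0))
  structure(list(airspeed = airspeed, t_min = t_min,
                 nightly_max_h = nightly_max_h, max_nights = max_nights,
                 oversea_max_h = oversea_max_h, max_legs = max_legs,
                 takeoff_local = takeoff_local, dusk_local = dusk_local,
                 dawn_local = dawn_local, altitudes_m = altitudes_m,
                 step_s = step_s, takeoff_tolerance_h = takeoff_tolerance_h,
                 calm_threshold = calm_threshold),
            class = "flight_params")
}

#' Ground velocity of a downwind-flying moth
#'
#' The moth's own airspeed is added along the wind unit vector (pure downwind
#' flight, no heading offset). In near-calm air the downwind heading is
#' undefined, so the wind vector is returned unchanged.
#'
#' @param u,v Wind components (m/s); vectorised.
#' @param airspeed Self-powered airspeed (m/s).
#' @param calm_threshold Wind speed below which the self-powered vector is
#'   suppressed (m/s).
#' @return A tibble with columns `u`, `v`: the ground-velocity components.
#' @examples
#' ground_velocity(4, 3, airspeed = 3)  # 6.4, 4.8
#' @export
ground_velocity <- function(u, v, airspeed = 3.0, calm_threshold = 0.1) {
  spd <- sqrt(u^2 + v^2)
  f <- ifelse(spd >= calm_threshold, 1 + airspeed / spd, 1)
  tibble::tibble(u = u * f, v = v * f)
}

#' Is flight permitted at this temperature?
#'
#' Flight is prohibited strictly below the gate temperature; equality permits
#' flight.
#'
#' @param temperature Air temperature at flight altitude (degrees C).
#' @param params A [flight_params()] object.
#' @return Logical, vectorised over `temperature`.
#' @export
flight_permitted <- function(temperature, params = flight_params()) {
  temperature >= params$t_min
}

#' Local mean solar time helpers
#'
#' The model uses local mean solar time, `local = UTC + lon / 15` hours,
#' because sites and candidate sources span several civil time zones while the
#' behavioural rules are stated as round local clock times.
#'
#' @param time_utc `POSIXct` (UTC).
#' @param lon Longitude in degrees (east positive).
#' @return `local_solar_hour()`: decimal hour of day in [0, 24).
#' @export
local_solar_hour <- function(time_utc, lon) {
  secs <- as.numeric(as.POSIXct(time_utc, tz = "UTC")) + lon / 15 * 3600
  (secs / 3600) %% 24
}

#' Nocturnal flight window for a date and longitude
#'
#' Returns the take-off and dawn instants (UTC) for the night that begins on
#' the given calendar date: take-off at `takeoff_local` on `date` (local mean
#' solar time) and dawn at `dawn_local` the following morning.
#'
#' @param date A `Date` (the evening the night begins).
#' @param lon Longitude in degrees.
#' @param params A [flight_params()] object.
#' @return A tibble with `takeoff_utc`, `dawn_utc` (`POSIXct`, UTC) and
#'   `window_h`, the take-off-to-dawn span in hours.
#' @examples
#' night_window(as.Date("2020-01-14"), lon = 142.5)
#' @export
night_window <- function(date, lon, params = flight_params()) {
  date <- as.Date(date)
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  offset_s <- lon / 15 * 3600
  takeoff <- midnight + params$takeoff_local * 3600 - offset_s
  dawn <- midnight + 86400 + params$dawn_local * 3600 - offset_s
  tibble::tibble(takeoff_utc = takeoff, dawn_utc = dawn,
                 window_h = as.numeric(difftime(dawn, takeoff, units = "hours")))
}

#' @rdname local_solar_hour
#' @param hour_local Decimal clock hour (e.g. `19` for 19:00).
#' @return `prev_local_clock_utc()`: the latest UTC instant at or before
#'   `time_utc` at which the local solar clock at `lon` reads `hour_local`;
#'   the backward integrator uses it to find candidate take-off instants.
#' @export
prev_local_clock_utc <- function(time_utc, lon, hour_local) {
  t <- as.POSIXct(time_utc, tz = "UTC")
  secs <- as.numeric(t)
  local <- secs + lon / 15 * 3600
  day0 <- floor(local / 86400) * 86400
  cand <- day0 + hour_local * 3600
  cand <- ifelse(cand > local, cand - 86400, cand)
  as.POSIXct(cand - lon / 15 * 3600, origin = "1970-01-01", tz = "UTC")
}
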
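# Nocturnal wind climatology: multi-level wind samples, 16-sector wind roses,
# sector-group frequencies, and time-height omega profiles with downdraft
# events.

SECTOR_NAMES <- c("N", "NNE", "NE", "ENE", "E", "ESE", "SE", "SSE",
                  "S", "SSW", "SW", "WSW", "W", "WNW", "NW", "NNW")

#' Meteorological wind direction
#'
#' The compass direction the wind blows *from* (0 = northerly, 90 = easterly,
#' 270 = westerly), computed as `atan2(-u, -v)` in degrees mod 360.
#'
#' @param u,v Wind components (m/s), vectorised.
#' @return Direction in degrees `[0, 360)`; `NA` for calm air (both
#'   components below 1e-8 in magnitude), which is excluded from roses.
#' @examples
#' met_direction(10, 0)  # 270: a westerly
#' @export
met_direction <- function(u, v) {
  calm <- abs(u) < 1e-8 & abs(v) < 1e-8
  d <- (atan2(-u, -v) * 180 / pi) %% 360
  d[calm] <- NA_real_
  d
}

#' Compass sector of a wind direction
#'
#' Sixteen half-open 22.5-degree bins centred on the compass points: sector
#' `k` covers `[k * 22.5 - 11.25, k * 22.5 + 11.25)` mod 360, so a boundary
#' direction belongs to the higher sector.
#'
#' @param direction Degrees in `[0, 360)`.
#' @return Integer sector index 0..15 (0 = N, 4 = E, 8 = S, 12 = W).
#' @export
sector_of <- function(direction) {
  stopifnot(all(is.na(direction) | (direction >= 0 & direction < 360)))
  as.integer(floor(((direction + 11.25) %% 360) / 22.5))
}

#' Nocturnal wind samples at sites and pressure levels
#'
#' Samples the wind at each site and pressure level for every nocturnal hour
#' (local mean solar time) of the requested months and years, then averages
#' the wind *vector* over the nights of each month: one sample per
#' (site, level, hour, year, month). That stratification makes the sample
#' count per monthly histogram exactly
#' `sites x levels x hours x years`. Set `monthly_mean = FALSE` to keep raw
#' per-night samples instead.
#'
#' @param fields A [met_field()] or list of them (e.g. one per year); each
#'   query instant is answered by the first field covering it.
#' @param sites A data frame with columns `site`, `lon`, `lat`.
#' @param levels_hpa Pressure levels (hPa), converted to sampling heights via
#'   [height_from_pressure()].
#' @param months,years Integer vectors selecting the climatology period.
#' @param hours_local Local-solar clock hours of the nocturnal window
#'   (default 20:00 through 05:00).
#' @param monthly_mean Average the wind vector over each month's nights
#'   (default) or return raw per-night samples.
#' @param mean_temperature Passed to [height_from_pressure()].
#' @return A `wind_samples` tibble: `site`, `year`, `month`, `hour_local`,
#'   `level_hpa`, `u`, `v`, `speed`, `direction_from`, `n_nights`,
#'   `n_missing`. Instants not covered by any field are reported through
#'   `n_missing` (and dropped entirely when a whole stratum is uncovered,
#'   with a warning).
#' @export
nightly_level_samples <- function(fields, sites, levels_hpa = c(800, 825, 850, 875, 900),
                                  months = 1:12, years = 2010:2019,
                                  hours_local = c(20:23, 0:5),
                                  monthly_mean = TRUE, mean_temperature = 288) {
  if (inherits(fields, "met_field")) fields <- list(fields)
  stopifnot(all(c("site", "lon", "lat") %in% names(sites)))
  heights <- height_from_pressure(levels_hpa, mean_temperature = mean_temperature)

  grid <- tidyr::expand_grid(site = sites$site, year = years, month = months,
                             hour_local = hours_local, level_hpa = levels_hpa)
  grid <- dplyr::left_join(grid, sites, by = "site")
  grid$height_m <- heights[match(grid$level_hpa, levels_hpa)]

  # expand each stratum over the nights of its month; a night is labelled by
  # the date of its evening, so post-midnight hours fall on the next day
  nights <- dplyr::distinct(grid, year, month)
  nights <- purrr::pmap_dfr(nights, function(year, month) {
    d0 <- as.Date(sprintf("%d-%02d-01", year, month))
    ndays <- as.integer(format(seq(d0, by = "1 month", length.out = 2)[2] - 1, "%d"))
    tibble::tibble(year = year, month = month, night = seq_len(ndays), date0 = d0)
  })
  full <- dplyr::inner_join(grid, nights, by = c("year", "month"),
                            relationship = "many-to-many")
  local_midnight <- as.numeric(as.POSIXct(paste(format(full$date0), "00:00:00"), tz = "UTC")) +
    (full$night - 1 + (full$hour_local < 12)) * 86400
  full$t_utc <- local_midnight + full$hour_local * 3600 - full$lon / 15 * 3600

  full$u <- NA_real_; full$v <- NA_real_
  unassigned <- rep(TRUE, nrow(full))
  for (f in fields) {
    tv <- as.numeric(f$times)
    sel <- unassigned & full$t_utc >= tv[1] & full$t_utc <= tv[length(tv)]
    if (!any(sel)) next
    s <- sample_atmosphere(f, full$t_utc[sel], full$lon[sel], full$lat[sel],
                           full$height_m[sel])
    full$u[sel] <- s$u; full$v[sel] <- s$v
    unassigned[sel] <- FALSE
  }
  full$ok <- !is.na(full$u)

  if (monthly_mean) {
    res <- dplyr::summarise(
      dplyr::group_by(full, site, year, month, hour_local, level_hpa),
      u = mean(u[ok]), v = mean(v[ok]),
      n_nights = sum(ok), n_missing = sum(!ok), .groups = "drop")
  } else {
    res <- dplyr::select(dplyr::filter(full, ok),
                         site, year, month, hour_local, level_hpa, night, u, v)
    res$n_nights <- 1L
    res$n_missing <- 0L
  }
  n_empty <- if (monthly_mean) sum(res$n_nights == 0) else 0L
  if (n_empty > 0) {
    warning(sprintf("%d strata had no met-field coverage and were dropped", n_empty),
            call. = FALSE)
    res <- dplyr::filter(res, .data$n_nights > 0)
  }
  res <- dplyr::mutate(res,
                       speed = sqrt(u^2 + v^2),
                       direction_from = met_direction(u, v))
  tibble::new_tibble(res, class = "wind_samples")
}

#' Monthly wind rose
#'
#' Tallies a month's wind samples into the sixteen 22.5-degree sectors:
#' counts, frequencies and per-sector mean speed.
#'
#' @param samples A `wind_samples` tibble from [nightly_level_samples()].
#' @param month Calendar month (1-12).
#' @return A `wind_rose` tibble with one row per sector (`sector`, `name`,
#'   `count`, `frequency`, `mean_speed`); attributes `month` and `total`.
#'   Calm samples (undefined direction) are excluded.
#' @export
monthly_wind_rose <- function(samples, month) {
  m <- dplyr::filter(samples, .data$month == !!month, !is.na(.data$direction_from))
  if (nrow(m) == 0) {
    stop(sprintf("no samples for month %d", month), call. = FALSE)
  }
  m$sector <- sector_of(m$direction_from)
  tal <- dplyr::summarise(dplyr::group_by(m, sector),
                          count = dplyr::n(), mean_speed = mean(speed), .groups = "drop")
  rose <- dplyr::left_join(tibble::tibble(sector = 0:15, name = SECTOR_NAMES),
                           tal, by = "sector")
  rose$count[is.na(rose$count)] <- 0L
  rose$frequency <- rose$count / sum(rose$count)
  rose <- dplyr::select(rose, sector, name, count, frequency, mean_speed)
  out <- tibble::new_tibble(rose, class = "wind_rose")
  attr(out, "month") <- month
  attr(out, "total") <- sum(rose$count)
  out
}

#' Frequency and mean speed of a sector group
#'
#' Share of samples whose direction falls in a group of compass sectors
#' (e.g. the westerly sectors), and the mean wind speed over those samples.
#'
#' @param samples A `wind_samples` tibble.
#' @param months Months to pool.
#' @param sectors Integer sector indices 0..15, or sector names such as
#'   `c("WSW", "W", "WNW")`.
#' @return A one-row tibble: `frequency_pct`, `mean_speed`, `n_in_group`,
#'   `n_total`.
#' @export
sector_group_stats <- function(samples, months, sectors) {
  if (is.character(sectors)) sectors <- match(sectors, SECTOR_NAMES) - 1L
  stopifnot(length(sectors) > 0, all(sectors %in% 0:15))
  m <- dplyr::filter(samples, .data$month %in% months, !is.na(.data$direction_from))
  sec <- sector_of(m$direction_from)
  in_group <- sec %in% sectors
  tibble::tibble(frequency_pct = 100 * mean(in_group),
                 mean_speed = mean(m$speed[in_group]),
                 n_in_group = sum(in_group), n_total = nrow(m))
}

#' Time-height profile of vertical pressure velocity
#'
#' Samples omega at one site over a time window and a stack of pressure
#' levels (the layer where descending air could force migrating moths down).
#'
#' @param field A [met_field()].
#' @param site_lon,site_lat Site coordinates (degrees).
#' @param levels_hpa Pressure levels (hPa).
#' @param window Optional length-2 `POSIXct` restricting the time range
#'   (defaults to the field span).
#' @param mean_temperature Passed to [height_from_pressure()].
#' @return A `vv_profile` tibble: `time`, `level_hpa`, `height_m`, `omega`.
#' @export
vertical_velocity_profile <- function(field, site_lon, site_lat,
                                      levels_hpa = seq(800, 950, by = 25),
                                      window = NULL, mean_temperature = 288) {
  stopifnot(inherits(field, "met_field"))
  times <- field$times
  if (!is.null(window)) {
    window <- as.POSIXct(window, tz = "UTC")
    times <- times[times >= window[1] & times <= window[2]]
  }
  if (length(times) == 0) stop("no field times in the requested window", call. = FALSE)
  heights <- height_from_pressure(levels_hpa, mean_temperature = mean_temperature)
  grid <- tidyr::expand_grid(time = times, level_hpa = levels_hpa)
  grid$height_m <- heights[match(grid$level_hpa, levels_hpa)]
  s <- sample_atmosphere(field, grid$time, site_lon, site_lat, grid$height_m)
  n_bad <- sum(!s$in_domain)
  if (n_bad > 0) {
    warning(sprintf("%d profile cells fall outside the field domain", n_bad), call. = FALSE)
  }
  out <- dplyr::mutate(grid, omega = s$omega)
  out <- tibble::new_tibble(out, class = "vv_profile")
  attr(out, "site") <- c(lon = site_lon, lat = site_lat)
  out
}

#' Detect downdraft events in an omega profile
#'
#' Maximal time intervals during which descending motion at any level meets
#' the threshold (inclusive by default: a boundary value counts as an event).
#' Each event also reports whether the equivalent vertical air speed
#' ([omega_to_vertical_ms()] at the strongest cell) exceeds the moth's
#' self-powered airspeed -- the test of whether a downdraft could force the
#' moth down.
#'
#' @param profile A `vv_profile` from [vertical_velocity_profile()].
#' @param threshold Omega threshold (Pa/s).
#' @param inclusive Treat omega exactly at the threshold as an exceedance.
#' @param airspeed Moth self-powered airspeed (m/s) for the overwhelm flag.
#' @param mean_temperature_k Air temperature (K) used in the omega-to-speed
#'   conversion.
#' @return A tibble with one row per event: `start`, `end`, `duration_h`,
#'   `max_omega`, `w_ms` (vertical speed at the peak, m/s, negative =
#'   downward) and `overwhelms_airspeed`.
#' @export
downdraft_events <- function(profile, threshold = 0.3, inclusive = TRUE,
                             airspeed = 3.0, mean_temperature_k = 288) {
  stopifnot(inherits(profile, "vv_profile"))
  by_t <- dplyr::summarise(dplyr::group_by(profile, time),
                           max_omega = max(omega, na.rm = TRUE),
                           peak_level = level_hpa[which.max(omega)],
                           .groups = "drop")
  by_t <- dplyr::arrange(by_t, time)
  eps <- 1e-9 * max(1, abs(threshold))
  hit <- if (inclusive) by_t$max_omega >= threshold - eps else by_t$max_omega > threshold + eps
  if (!any(hit)) {
    return(tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_h = numeric(), max_omega = numeric(),
                          w_ms = numeric(), overwhelms_airspeed = logical()))
  }
  run_id <- cumsum(c(1L, diff(hit) != 0))
  events <- purrr::map_dfr(unique(run_id[hit]), function(id) {
    seg <- by_t[run_id == id & hit, ]
    pk <- which.max(seg$max_omega)
    w <- omega_to_vertical_ms(seg$max_omega[pk], seg$peak_level[pk] * 100,
                              mean_temperature_k)
    tibble::tibble(start = seg$time[1], end = seg$time[nrow(seg)],
                   duration_h = as.numeric(difftime(seg$time[nrow(seg)], seg$time[1],
                                                    units = "hours")),
                   max_omega = max(seg$max_omega), w_ms = w,
                   overwhelms_airspeed = abs(w) > airspeed)
  })
  events
}
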
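# Forward/backward trajectory integration under the nocturnal flight rules:
# midpoint (RK2) stepping on a sphere, dusk/dawn window logic, over-sea
# extension with a hard 36 h cap, the low-temperature flight gate, and the
# stepping-stone multi-leg backward reconstruction.

# Per-field grid metadata so the inner-loop sampler can index regular axes
# arithmetically instead of via findInterval.
.grid_info <- function(field) {
  axis <- function(x) {
    n <- length(x)
    regular <- n >= 2 && max(abs(diff(x) - (x[2] - x[1]))) < 1e-6 * abs(x[2] - x[1])
    list(x0 = x[1], dx = if (n >= 2) x[2] - x[1] else 1, n = n,
         vals = x, regular = regular)
  }
  list(t = axis(as.numeric(field$times)), l = axis(field$levels),
       a = axis(field$lats), o = axis(field$lons))
}

.axis_locate <- function(ax, x) {
  if (ax$regular) {
    fi <- (x - ax$x0) / ax$dx + 1
    i <- floor(fi)
    if (i < 1) i <- 1L else if (i >= ax$n) i <- ax$n - 1L
    c(i, fi - i)
  } else {
    i <- findInterval(x, ax$vals)
    if (i < 1L) i <- 1L else if (i >= ax$n) i <- ax$n - 1L
    c(i, (x - ax$vals[i]) / (ax$vals[i + 1L] - ax$vals[i]))
  }
}

# Lean scalar atmosphere sample used inside the integrator loop (the exported
# sample_atmosphere() carries tibble overhead that matters at ~1e5 calls).
.sample1 <- function(field, t_s, lon, lat, alt) {
  gi <- attr(field, "grid_info")
  if (is.null(gi)) gi <- .grid_info(field)
  tv <- gi$t$vals; lev <- gi$l$vals; las <- gi$a$vals; los <- gi$o$vals
  d1 <- gi$t$n; d2 <- gi$l$n; d3 <- gi$a$n; d4 <- gi$o$n
  if (t_s < tv[1] || t_s > tv[d1] ||
      alt < lev[1] || alt > lev[d2] ||
      lat < las[1] || lat > las[d3] ||
      lon < los[1] || lon > los[d4]) {
    return(NULL)
  }
  bt <- .axis_locate(gi$t, t_s); bl <- .axis_locate(gi$l, alt)
  ba <- .axis_locate(gi$a, lat); bo <- .axis_locate(gi$o, lon)
  ti <- bt[1]; li <- bl[1]; ai <- ba[1]; oi <- bo[1]
  ft <- bt[2]; fl <- bl[2]; fa <- ba[2]; fo <- bo[2]
  i0 <- ti + d1 * ((li - 1L) + d2 * ((ai - 1L) + d3 * (oi - 1L)))
  st <- 1L; sl <- d1; sa <- d1 * d2; so <- d1 * d2 * d3
  idx <- c(i0, i0 + st, i0 + sl, i0 + st + sl,
           i0 + sa, i0 + st + sa, i0 + sl + sa, i0 + st + sl + sa,
           i0 + so, i0 + st + so, i0 + sl + so, i0 + st + sl + so,
           i0 + sa + so, i0 + st + sa + so, i0 + sl + sa + so,
           i0 + st + sl + sa + so)
  wt1 <- 1 - ft; wl1 <- 1 - fl; wa1 <- 1 - fa; wo1 <- 1 - fo
  w <- c(wt1 * wl1, ft * wl1, wt1 * fl, ft * fl)
  w <- c(w * wa1, w * fa)
  w <- c(w * wo1, w * fo)
  list(u = sum(w * field$u[idx]), v = sum(w * field$v[idx]),
       temperature = sum(w * field$temperature[idx]),
       omega = sum(w * field$omega[idx]))
}

# scalar numeric twin of prev_local_clock_utc (seconds since epoch)
.prev_clock_s <- function(t_s, lon, hour_local) {
  local <- t_s + lon * 240
  cand <- floor(local / 86400) * 86400 + hour_local * 3600
  if (cand > local) cand <- cand - 86400
  cand - lon * 240
}

# scalar nearest-cell land lookup on a regular mask grid
.is_land1 <- function(mask, lon, lat) {
  la <- mask$lats; lo <- mask$lons
  if (lat < la[1] || lat > la[length(la)] || lon < lo[1] || lon > lo[length(lo)]) {
    return(FALSE)
  }
  i <- round((lat - la[1]) / (la[2] - la[1])) + 1L
  j <- round((lon - lo[1]) / (lo[2] - lo[1])) + 1L
  mask$land[i, j]
}

.ground_uv <- function(s, params) {
  spd <- sqrt(s$u^2 + s$v^2)
  if (spd >= params$calm_threshold) {
    f <- 1 + params$airspeed / spd
    c(s$u * f, s$v * f)
  } else c(s$u, s$v)
}

# One RK2 (midpoint) step; sgn = +1 forward, -1 backward (the full ground
# velocity, wind plus self-powered vector, is negated when integrating back).
.rk2 <- function(field, params, t_s, lon, lat, alt, sgn) {
  dt <- params$step_s
  s1 <- .sample1(field, t_s, lon, lat, alt)
  if (is.null(s1)) return(NULL)
  g1 <- .ground_uv(s1, params)
  lat_mid <- lat + sgn * g1[2] * dt / 2 / DEG_M
  lon_mid <- lon + sgn * g1[1] * dt / 2 / (DEG_M * cos(lat * pi / 180))
  s2 <- .sample1(field, t_s + sgn * dt / 2, lon_mid, lat_mid, alt)
  if (is.null(s2)) return(NULL)
  g2 <- .ground_uv(s2, params)
  lat_new <- lat + sgn * g2[2] * dt / DEG_M
  lon_new <- lon + sgn * g2[1] * dt / (DEG_M * cos(lat_mid * pi / 180))
  list(t_s = t_s + sgn * dt, lon = lon_new, lat = lat_new)
}

#' Advance a trajectory state by one integration step
#'
#' A single midpoint (RK2) step of `step_s` seconds. Displacement follows the
#' downwind ground velocity ([ground_velocity()]); metres are converted to
#' degrees on a sphere of radius 6371 km with the cos-latitude metric, and
#' altitude is held constant AGL. Backward stepping negates the full ground
#' velocity.
#'
#' @param state A list or one-row data frame with `time` (`POSIXct`, UTC),
#'   `lon`, `lat` (degrees) and `altitude_m`.
#' @param field A [met_field()].
#' @param params A [flight_params()].
#' @param direction `"forward"` or `"backward"`.
#' @return A one-row tibble with the new `time`, `lon`, `lat`, `altitude_m`
#'   and `in_domain`; when the step leaves the grid, the input state is
#'   returned with `in_domain = FALSE`.
#' @export
advance <- function(state, field, params = flight_params(),
                    direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "forward") 1 else -1
  t_s <- as.numeric(as.POSIXct(state$time, tz = "UTC"))
  res <- .rk2(field, params, t_s, state$lon, state$lat, state$altitude_m, sgn)
  if (is.null(res)) {
    return(tibble::tibble(time = as.POSIXct(state$time, tz = "UTC"),
                          lon = state$lon, lat = state$lat,
                          altitude_m = state$altitude_m, in_domain = FALSE))
  }
  tibble::tibble(time = as.POSIXct(res$t_s, origin = "1970-01-01", tz = "UTC"),
                 lon = res$lon, lat = res$lat, altitude_m = state$altitude_m,
                 in_domain = TRUE)
}

.new_trajectory <- function(mat, n, direction, leg_index, reason, release, params) {
  pts <- tibble::tibble(
    time = as.POSIXct(mat[seq_len(n), 1], origin = "1970-01-01", tz = "UTC"),
    lon = mat[seq_len(n), 2], lat = mat[seq_len(n), 3],
    altitude_m = mat[seq_len(n), 4],
    u = mat[seq_len(n), 5], v = mat[seq_len(n), 6],
    temperature = mat[seq_len(n), 7],
    surface = ifelse(mat[seq_len(n), 8] > 0, "land", "sea"))
  structure(list(points = pts, direction = direction, leg_index = leg_index,
                 termination_reason = reason,
                 flight_duration_h = abs(mat[n, 1] - mat[1, 1]) / 3600,
                 release = release),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  ep <- x$points[nrow(x$points), ]
  cat(sprintf("<trajectory> %s leg %d: %.1f h, %d points, ends (%.3f, %.3f) on %s [%s]\n",
              x$direction, x$leg_index, x$flight_duration_h, nrow(x$points),
              ep$lon, ep$lat, ep$surface, x$termination_reason))
  invisible(x)
}

#' Simulate one flight leg
#'
#' Integrates a single nocturnal flight under the behavioural rules, forward
#' or backward, until the first applicable stop:
#' the low-temperature gate (`"cold"`), the dusk/dawn boundary over land
#' (`"dawn_landfall"`: dawn landing for forward legs, the dusk take-off
#' instant for backward legs), first landfall when the boundary is crossed
#' over sea, the nightly over-land cap (`"nightly_cap"`), the hard over-sea
#' cap (`"oversea_cap"`), or leaving the grid (`"domain_exit"`).
#'
#' @param release A list or one-row data frame with `lon`, `lat`, `time`
#'   (`POSIXct`, UTC), `altitude_m` and `direction` (`"forward"` or
#'   `"backward"`).
#' @param field A [met_field()].
#' @param mask A [land_mask()].
#' @param params A [flight_params()].
#' @param leg_index Leg number carried on the result (1 = the flight nearest
#'   arrival in a backward reconstruction).
#' @return A `trajectory` object; see [tidy.trajectory()] for the point table.
#' @export
run_leg <- function(release, field, mask, params = flight_params(), leg_index = 1L) {
  direction <- match.arg(release$direction, c("forward", "backward"))
  sgn <- if (direction == "forward") 1 else -1
  t0 <- as.numeric(as.POSIXct(release$time, tz = "UTC"))
  tv <- as.numeric(field$times)
  if (t0 < tv[1] || t0 > tv[length(tv)]) {
    stop("release time is outside the met-field time span", call. = FALSE)
  }
  attr(field, "grid_info") <- .grid_info(field)
  lon <- release$lon; lat <- release$lat; alt <- release$altitude_m
  s <- .sample1(field, t0, lon, lat, alt)
  if (is.null(s)) stop("release point is outside the met-field grid", call. = FALSE)

  n_max <- ceiling(params$oversea_max_h * 3600 / params$step_s) + 2L
  mat <- matrix(NA_real_, n_max, 8)
  record <- function(k, t_s, lon, lat, s, land) {
    mat[k, ] <<- c(t_s, lon, lat, alt, s$u, s$v, s$temperature, land)
  }
  # fast nearest-cell lookup needs a regular mask grid; fall back otherwise
  reg <- function(x) length(x) < 3 || max(abs(diff(diff(x)))) < 1e-9
  land_at <- if (reg(mask$lats) && reg(mask$lons)) {
    function(lon, lat) .is_land1(mask, lon, lat)
  } else {
    function(lon, lat) is_land(mask, lon, lat)
  }
  land0 <- land_at(lon, lat)
  record(1L, t0, lon, lat, s, land0)
  if (s$temperature < params$t_min) {
    return(.new_trajectory(mat, 1L, direction, leg_index, "cold", release, params))
  }

  if (direction == "forward") {
    p <- .prev_clock_s(t0, lon, params$dawn_local)
    dawn_s <- p + if (p < t0) 86400 else 0
    window_h <- (dawn_s - t0) / 3600
    land_limit_h <- min(params$nightly_max_h, window_h)
    past_dawn <- FALSE
  }

  # take a partial step from a saved state onto an exact clock instant, so
  # dusk/dawn endpoints do not inherit the step-size quantisation
  partial_to <- function(t_from, lon_from, lat_from, t_target) {
    p0 <- params
    p0$step_s <- abs(t_target - t_from)
    if (p0$step_s < 1e-9) {
      list(t_s = t_target, lon = lon_from, lat = lat_from)
    } else {
      .rk2(field, p0, t_from, lon_from, lat_from, alt, sgn)
    }
  }
  k <- 1L; t_s <- t0; reason <- NULL
  while (is.null(reason)) {
    stp <- .rk2(field, params, t_s, lon, lat, alt, sgn)
    if (is.null(stp)) { reason <- "domain_exit"; break }
    s_new <- .sample1(field, stp$t_s, stp$lon, stp$lat, alt)
    if (is.null(s_new)) { reason <- "domain_exit"; break }
    if (s_new$temperature < params$t_min) { reason <- "cold"; break }
    t_prev <- t_s; lon_prev <- lon; lat_prev <- lat
    t_s <- stp$t_s; lon <- stp$lon; lat <- stp$lat
    k <- k + 1L
    land <- land_at(lon, lat)
    record(k, t_s, lon, lat, s_new, land)
    elapsed_h <- abs(t_s - t0) / 3600
    if (direction == "forward") {
      # dawn at the moth's own longitude: the local solar clock is carried
      # with the moving position, mirroring the backward take-off rule
      if (!past_dawn) {
        p <- .prev_clock_s(t_s, lon, params$dawn_local)
        if (p > t_prev) {
          ps <- partial_to(t_prev, lon_prev, lat_prev, p)
          if (!is.null(ps) && land_at(ps$lon, ps$lat)) {
            sp <- .sample1(field, ps$t_s, ps$lon, ps$lat, alt)
            t_s <- ps$t_s; lon <- ps$lon; lat <- ps$lat
            record(k, t_s, lon, lat, sp, TRUE)
            reason <- "dawn_landfall"; break
          }
          past_dawn <- TRUE
        }
      }
      if (past_dawn && land) { reason <- "dawn_landfall"; break }
      if (!past_dawn && land && elapsed_h >= land_limit_h) { reason <- "nightly_cap"; break }
    } else {
      cross <- .prev_clock_s(t_prev, lon, params$takeoff_local)
      if (cross >= t_s && cross < t_prev) {
        ps <- partial_to(t_prev, lon_prev, lat_prev, cross)
        if (!is.null(ps) && land_at(ps$lon, ps$lat)) {
          sp <- .sample1(field, ps$t_s, ps$lon, ps$lat, alt)
          t_s <- ps$t_s; lon <- ps$lon; lat <- ps$lat
          record(k, t_s, lon, lat, sp, TRUE)
          reason <- "dawn_landfall"; break
        }
      }
    }
    if (elapsed_h >= params$oversea_max_h) { reason <- "oversea_cap"; break }
    if (k >= n_max) { reason <- "oversea_cap"; break }
  }
  .new_trajectory(mat, k, direction, leg_index, reason, release, params)
}

.release_hours <- function(params) {
  if (params$dusk_local > params$dawn_local) {
    c(seq(params$dusk_local, 23), seq(0, params$dawn_local))
  } else {
    seq(params$dusk_local, params$dawn_local)
  }
}

.release_utc <- function(night_date, hour_local, lon) {
  night_date <- as.Date(night_date)
  date <- if (hour_local >= 12) night_date else night_date + 1
  as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC") +
    hour_local * 3600 - lon / 15 * 3600
}

#' Launch a fan of hourly backward trajectories
#'
#' One backward leg per combination of nocturnal release hour (hourly from
#' dusk to the following dawn, local mean solar time) and candidate flight
#' altitude: 10 hours x 8 altitudes = 80 legs for the defaults.
#'
#' @param arrival_lon,arrival_lat Arrival point (degrees).
#' @param arrival_night The calendar date on which the arrival night begins
#'   (its evening).
#' @param field A [met_field()].
#' @param mask A [land_mask()].
#' @param params A [flight_params()].
#' @param hours_local,altitudes_m Optional restrictions of the release grid.
#' @param leg_index Leg number stamped on each trajectory.
#' @return A `trajectory_fan` tibble: one row per candidate with
#'   `release_hour`, `altitude_m`, `release_time`, endpoint coordinates and
#'   time, `termination_reason`, `duration_h`, `end_on_land` and the
#'   `trajectory` object in a list column.
#' @export
run_backward_fan <- function(arrival_lon, arrival_lat, arrival_night,
                             field, mask, params = flight_params(),
                             hours_local = NULL, altitudes_m = NULL,
                             leg_index = 1L) {
  hours_local <- if (is.null(hours_local)) .release_hours(params) else hours_local
  altitudes_m <- if (is.null(altitudes_m)) params$altitudes_m else altitudes_m
  grid <- tidyr::expand_grid(release_hour = hours_local, altitude_m = altitudes_m)
  trajs <- purrr::pmap(grid, function(release_hour, altitude_m) {
    rel <- list(lon = arrival_lon, lat = arrival_lat,
                time = .release_utc(arrival_night, release_hour, arrival_lon),
                altitude_m = altitude_m, direction = "backward")
    run_leg(rel, field, mask, params, leg_index = leg_index)
  })
  out <- dplyr::mutate(
    grid,
    release_time = as.POSIXct(purrr::map_dbl(trajs, ~ as.numeric(.x$points$time[1])),
                              origin = "1970-01-01", tz = "UTC"),
    trajectory = trajs,
    termination_reason = purrr::map_chr(trajs, "termination_reason"),
    duration_h = purrr::map_dbl(trajs, "flight_duration_h"),
    end_lon = purrr::map_dbl(trajs, ~ .x$points$lon[nrow(.x$points)]),
    end_lat = purrr::map_dbl(trajs, ~ .x$points$lat[nrow(.x$points)]),
    end_time = as.POSIXct(purrr::map_dbl(trajs, ~ as.numeric(.x$points$time[nrow(.x$points)])),
                          origin = "1970-01-01", tz = "UTC"),
    end_on_land = purrr::map_lgl(trajs, ~ .x$points$surface[nrow(.x$points)] == "land")
  )
  out <- tibble::new_tibble(out, class = "trajectory_fan")
  attr(out, "arrival") <- c(lon = arrival_lon, lat = arrival_lat)
  attr(out, "arrival_night") <- as.Date(arrival_night)
  attr(out, "params") <- params
  out
}

#' Stepping-stone multi-leg backward reconstruction
#'
#' Runs the arrival-night backward fan, then, for every leg whose endpoint is
#' a plausible take-off (on land, near the local take-off time), treats that
#' endpoint as the previous flight's landing site and launches a second
#' backward fan across the preceding night's hourly landing times. Qualifying
#' endpoints are grouped by mask grid cell, one second-leg fan per cell.
#' Chaining stops at `params$max_legs`.
#'
#' @inheritParams run_backward_fan
#' @return A `multileg_paths` tibble: one row per candidate path (single-leg
#'   paths plus every chained two-leg combination), with per-leg release
#'   hour/altitude, stopover and final-endpoint coordinates, and the ordered
#'   list of `trajectory` legs in the `legs` list column. Endpoint validity is
#'   assessed by [filter_and_count()].
#' @export
run_multileg_backward <- function(arrival_lon, arrival_lat, arrival_night,
                                  field, mask, params = flight_params(),
                                  hours_local = NULL, altitudes_m = NULL) {
  fan1 <- run_backward_fan(arrival_lon, arrival_lat, arrival_night,
                           field, mask, params, hours_local, altitudes_m,
                           leg_index = 1L)
  rows <- vector("list", 0L)
  leg1_path <- function(i) {
    tr <- fan1$trajectory[[i]]
    tibble::tibble(
      n_legs = 1L,
      leg1_release_hour = fan1$release_hour[i], leg1_altitude_m = fan1$altitude_m[i],
      leg2_release_hour = NA_real_, leg2_altitude_m = NA_real_,
      stopover_lon = NA_real_, stopover_lat = NA_real_, stopover_cell = NA_character_,
      end_lon = fan1$end_lon[i], end_lat = fan1$end_lat[i],
      end_time = fan1$end_time[i],
      termination_reason = fan1$termination_reason[i],
      legs = list(list(tr)))
  }
  rows <- purrr::map(seq_len(nrow(fan1)), leg1_path)

  chainable <- purrr::map_lgl(fan1$trajectory,
                              ~ .chainable_endpoint(.x, mask, params))
  leg2_fans <- list()
  if (params$max_legs >= 2 && any(chainable)) {
    idx <- which(chainable)
    cell_la <- .nearest_idx(mask$lats, fan1$end_lat[idx])
    cell_lo <- .nearest_idx(mask$lons, fan1$end_lon[idx])
    cell <- paste(cell_la, cell_lo, sep = "_")
    for (cl in unique(cell)) {
      members <- idx[cell == cl]
      rep_i <- members[1]
      # local evening date at the stopover take-off = the night the previous
      # flight ended on; its landing window is the night beginning a day earlier
      ep_t <- as.numeric(fan1$end_time[rep_i])
      local_date <- as.Date(floor((ep_t + fan1$end_lon[rep_i] / 15 * 3600) / 86400),
                            origin = "1970-01-01")
      fan2 <- run_backward_fan(fan1$end_lon[rep_i], fan1$end_lat[rep_i],
                               local_date - 1, field, mask, params,
                               hours_local, altitudes_m, leg_index = 2L)
      leg2_fans[[cl]] <- fan2
      for (i in members) {
        tr1 <- fan1$trajectory[[i]]
        two <- purrr::map(seq_len(nrow(fan2)), function(j) {
          tibble::tibble(
            n_legs = 2L,
            leg1_release_hour = fan1$release_hour[i], leg1_altitude_m = fan1$altitude_m[i],
            leg2_release_hour = fan2$release_hour[j], leg2_altitude_m = fan2$altitude_m[j],
            stopover_lon = fan1$end_lon[i], stopover_lat = fan1$end_lat[i],
            stopover_cell = cl,
            end_lon = fan2$end_lon[j], end_lat = fan2$end_lat[j],
            end_time = fan2$end_time[j],
            termination_reason = fan2$termination_reason[j],
            legs = list(list(tr1, fan2$trajectory[[j]])))
        })
        rows <- c(rows, two)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, path_id = dplyr::row_number(), .before = 1)
  out <- tibble::new_tibble(out, class = "multileg_paths")
  attr(out, "arrival") <- c(lon = arrival_lon, lat = arrival_lat)
  attr(out, "arrival_night") <- as.Date(arrival_night)
  attr(out, "params") <- params
  attr(out, "leg2_fans") <- leg2_fans
  out
}

# A backward leg endpoint can seed a previous flight if it sits on land at a
# plausible dusk take-off and the leg terminated at that boundary.
.chainable_endpoint <- function(traj, mask, params) {
  if (traj$termination_reason != "dawn_landfall") return(FALSE)
  ep <- traj$points[nrow(traj$points), ]
  if (!is_land(mask, ep$lon, ep$lat)) return(FALSE)
  h <- local_solar_hour(ep$time, ep$lon)
  dh <- min(abs(h - params$takeoff_local), 24 - abs(h - params$takeoff_local))
  dh <= params$takeoff_tolerance_h
}

#' Integrate a fixed-duration drift without behavioural stops
#'
#' Steps a trajectory for exactly `duration_h` hours, ignoring the night
#' window, surface and temperature rules. Useful for kinematic checks such as
#' forward/backward inversion; stops early only on domain exit.
#'
#' @inheritParams run_leg
#' @param duration_h Integration time in hours.
#' @return A tibble of trajectory points (`time`, `lon`, `lat`, `altitude_m`).
#' @export
drift <- function(release, field, params = flight_params(), duration_h = 1,
                  direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "forward") 1 else -1
  attr(field, "grid_info") <- .grid_info(field)
  n_steps <- round(duration_h * 3600 / params$step_s)
  t_s <- as.numeric(as.POSIXct(release$time, tz = "UTC"))
  lon <- release$lon; lat <- release$lat; alt <- release$altitude_m
  mat <- matrix(NA_real_, n_steps + 1L, 3)
  mat[1L, ] <- c(t_s, lon, lat)
  k <- 1L
  for (i in seq_len(n_steps)) {
    stp <- .rk2(field, params, t_s, lon, lat, alt, sgn)
    if (is.null(stp)) break
    t_s <- stp$t_s; lon <- stp$lon; lat <- stp$lat
    k <- k + 1L
    mat[k, ] <- c(t_s, lon, lat)
  }
  tibble::tibble(time = as.POSIXct(mat[seq_len(k), 1], origin = "1970-01-01", tz = "UTC"),
                 lon = mat[seq_len(k), 2], lat = mat[seq_len(k), 3],
                 altitude_m = alt)
}
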
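test_that("one integration step matches the closed-form displacement", {
  fld <- make_uniform_field(10, 0, 25, extent = c(115, 150, -5, 5), res_deg = 1)
  st <- list(time = fld$times[5], lon = 130, lat = 0, altitude_m = 1000)
  a <- advance(st, fld)
  # 13 m/s for 300 s = 3900 m eastward at the equator
  expect_equal(a$lon - 130, 3900 / (6371000 * pi / 180), tolerance = 1e-9)
  expect_equal(a$lat, 0)
  # a backward step from the result returns to the start in constant flow
  b <- advance(a, fld, direction = "backward")
  expect_equal(b$lon, 130, tolerance = 1e-6)
  # cos-lat metric: at 60 degrees the same step covers twice the longitude
  fld60 <- make_uniform_field(10, 0, 25, extent = c(115, 150, 55, 65), res_deg = 1)
  a60 <- advance(list(time = fld60$times[5], lon = 130, lat = 60, altitude_m = 1000), fld60)
  expect_equal((a60$lon - 130) / (a$lon - 130), 1 / cos(60 * pi / 180), tolerance = 1e-3)
  # leaving the grid is flagged, not clamped
  edge <- advance(list(time = fld$times[5], lon = 149.99, lat = 0, altitude_m = 1000), fld)
  expect_false(edge$in_domain)
})

test_that("a 10 h drift in a 10 m/s wind covers 468 km within 0.1 %", {
  fld <- make_uniform_field(10, 0, 25, extent = c(115, 150, -15, -5), res_deg = 1)
  d <- drift(list(lon = 120, lat = -9.4, time = fld$times[3], altitude_m = 1500),
             fld, duration_h = 10)
  dist <- geosphere::distCosine(c(d$lon[1], d$lat[1]),
                                c(d$lon[nrow(d)], d$lat[nrow(d)]), r = 6371000)
  expect_equal(dist, 468000, tolerance = 1e-3)
})

test_that("flight legs stop by the rules: dawn over land, 36 h over sea, cold", {
  # meridional wind keeps the local clock fixed: the leg is the full 10 h window
  fld <- make_uniform_field(0, 10, 25, extent = c(140, 145, -20, 0), res_deg = 1,
                            duration_h = 48)
  rel <- list(lon = 142.5, lat = -17, time = as.POSIXct("2020-01-14 09:30:00", tz = "UTC"),
              altitude_m = 1500, direction = "forward")
  land <- mask_uniform(fld$lats, fld$lons, TRUE)
  tl <- run_leg(rel, fld, land)
  expect_equal(tl$termination_reason, "dawn_landfall")
  expect_equal(tl$flight_duration_h, 10, tolerance = 1e-6)
  expect_equal(tl$points$surface[nrow(tl$points)], "land")

  sea <- mask_uniform(fld$lats, fld$lons, FALSE)
  ts <- run_leg(rel, fld, sea)
  expect_equal(ts$termination_reason, "oversea_cap")
  expect_equal(ts$flight_duration_h, 36, tolerance = 1e-9)

  cold <- make_uniform_field(0, 10, 10, extent = c(140, 145, -20, 0), res_deg = 1)
  tc <- run_leg(rel, cold, land)
  expect_equal(tc$termination_reason, "cold")
  expect_equal(nrow(tc$points), 1L)
  expect_equal(tc$flight_duration_h, 0)

  expect_error(run_leg(list(lon = 142.5, lat = -17,
                            time = fld$times[1] - 86400,
                            altitude_m = 1500, direction = "forward"),
                       fld, land), "time span")
})

test_that("a shorter nightly cap cuts over-land flight before dawn", {
  fld <- make_uniform_field(0, 10, 25, extent = c(140, 145, -20, 0), res_deg = 1)
  land <- mask_uniform(fld$lats, fld$lons, TRUE)
  p8 <- flight_params(nightly_max_h = 8)
  tr <- run_leg(list(lon = 142.5, lat = -17,
                     time = as.POSIXct("2020-01-14 09:30:00", tz = "UTC"),
                     altitude_m = 1500, direction = "forward"), fld, land, p8)
  expect_equal(tr$termination_reason, "nightly_cap")
  expect_equal(tr$flight_duration_h, 8, tolerance = 0.1)
})

test_that("backward fans enumerate release hours times altitudes", {
  sc <- scenario_1leg()
  tr <- sc$truth
  fan <- run_backward_fan(tr$arrival_lon, tr$arrival_lat, tr$expected_arrival_night,
                          sc$field, sc$mask, altitudes_m = c(500))
  expect_equal(nrow(fan), 10L)
  expect_setequal(fan$release_hour, c(20:23, 0:5))
  full <- tidyr::expand_grid(release_hour = c(20:23, 0:5),
                             altitude_m = flight_params()$altitudes_m)
  expect_equal(10L * 8L, nrow(full))  # the default fan size
  # release instants follow local solar time at the arrival longitude
  expect_equal(local_solar_hour(fan$release_time, tr$arrival_lon),
               fan$release_hour %% 24, tolerance = 1e-9)
})

test_that("backward legs in the one-leg scenario reach the source at take-off time", {
  sc <- scenario_1leg()
  tr <- sc$truth
  fan <- run_backward_fan(tr$arrival_lon, tr$arrival_lat, tr$expected_arrival_night,
                          sc$field, sc$mask, altitudes_m = c(1000, 1500))
  hits <- purrr::keep(fan$trajectory, function(t) {
    ep <- t$points[nrow(t$points), ]
    t$termination_reason == "dawn_landfall" &&
      gc_km(c(ep$lon, ep$lat), c(tr$source_lon, tr$source_lat)) < tr$source_radius_km + 10
  })
  expect_gte(length(hits), 1)
  ep <- hits[[1]]$points[nrow(hits[[1]]$points), ]
  h <- local_solar_hour(ep$time, ep$lon)
  expect_lt(min(abs(h - 19), 24 - abs(h - 19)), 1)
})

test_that("forward and backward integration invert on smooth fields", {
  sc <- scenario_1leg()
  fld <- sc$field
  p60 <- flight_params(step_s = 60)
  set.seed(99)
  errs <- replicate(10, {
    lon0 <- runif(1, min(fld$lons) + 3, max(fld$lons) - 3)
    lat0 <- runif(1, min(fld$lats) + 1, max(fld$lats) - 1)
    alt <- sample(c(500, 1000, 1500, 2000), 1)
    t0 <- fld$times[1] + runif(1, 12, 60) * 3600
    fwd <- drift(list(lon = lon0, lat = lat0, time = t0, altitude_m = alt),
                 fld, p60, duration_h = 4, direction = "forward")
    stopifnot(nrow(fwd) == 241)
    end <- fwd[nrow(fwd), ]
    back <- drift(list(lon = end$lon, lat = end$lat, time = end$time, altitude_m = alt),
                  fld, p60, duration_h = 4, direction = "backward")
    gc_km(c(back$lon[nrow(back)], back$lat[nrow(back)]), c(lon0, lat0))
  })
  path_km <- 4 * (12 + 3) * 3.6
  expect_lt(max(errs), max(1, 0.002 * path_km))
})

test_that("halving the step moves smooth-field endpoints by well under 0.5 km", {
  sc <- scenario_1leg()
  tr <- sc$truth
  rel <- list(lon = tr$arrival_lon, lat = tr$arrival_lat,
              time = night_window(tr$expected_arrival_night, tr$arrival_lon)$dawn_utc,
              altitude_m = 1500, direction = "backward")
  e300 <- run_leg(rel, sc$field, sc$mask, flight_params(step_s = 300))
  e150 <- run_leg(rel, sc$field, sc$mask, flight_params(step_s = 150))
  p1 <- e300$points[nrow(e300$points), ]
  p2 <- e150$points[nrow(e150$points), ]
  expect_lt(gc_km(c(p1$lon, p1$lat), c(p2$lon, p2$lat)), 0.5)
})

test_that("multi-leg reconstruction respects the leg cap and chains at stopovers", {
  paths <- paths_2leg()
  expect_true(all(paths$n_legs <= flight_params()$max_legs))
  two <- dplyr::filter(paths, n_legs == 2)
  expect_gt(nrow(two), 0)
  # legs connect: leg-2 release sits within one grid cell of the leg-1 endpoint
  sc <- scenario_2leg()
  cell <- abs(diff(sc$mask$lons[1:2]))
  for (i in sample(nrow(two), 5)) {
    l1 <- two$legs[[i]][[1]]; l2 <- two$legs[[i]][[2]]
    ep1 <- l1$points[nrow(l1$points), ]
    expect_lt(abs(l2$points$lon[1] - ep1$lon), cell + 1e-9)
    expect_lt(abs(l2$points$lat[1] - ep1$lat), cell + 1e-9)
  }
  # a capped single-leg run never produces chained paths
  p1 <- run_multileg_backward(sc$truth$arrival_lon, sc$truth$arrival_lat,
                              sc$truth$expected_arrival_night, sc$field, sc$mask,
                              flight_params(max_legs = 1),
                              altitudes_m = c(1500))
  expect_true(all(p1$n_legs == 1))
})

test_that("one-leg scenarios yield no valid chained paths", {
  sc <- scenario_1leg()
  paths <- run_multileg_backward(sc$truth$arrival_lon, sc$truth$arrival_lat,
                                 sc$truth$expected_arrival_night, sc$field, sc$mask,
                                 altitudes_m = c(1000, 1500, 2000))
  rep <- filter_and_count(paths, sc$mask)
  valid <- dplyr::filter(rep$paths, valid)
  expect_gt(nrow(valid), 0)
  expect_true(all(valid$n_legs == 1))
})
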
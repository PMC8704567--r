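# Endpoint validity and report summaries, on hand-built fixtures plus the
# synthetic scenario.

land_everywhere <- mask_uniform(seq(-12, -8, 0.5), seq(138, 146, 0.5), TRUE)
sea_everywhere <- mask_uniform(seq(-12, -8, 0.5), seq(138, 146, 0.5), FALSE)
# 19:00 local at lon 142.5 is 09:30 UTC
t_takeoff <- as.POSIXct("2020-01-14 09:30:00", tz = "UTC")

test_that("endpoint validity needs land, take-off time and a clean stop", {
  ok <- stub_trajectory(142.5, -10, t_takeoff)
  expect_true(endpoint_valid(ok, land_everywhere))
  expect_false(endpoint_valid(ok, sea_everywhere))                       # over sea
  late <- stub_trajectory(142.5, -10, t_takeoff - 6 * 3600)              # 13:00 local
  expect_false(endpoint_valid(late, land_everywhere))
  cold <- stub_trajectory(142.5, -10, t_takeoff, reason = "cold")
  expect_false(endpoint_valid(cold, land_everywhere))
  exited <- stub_trajectory(142.5, -10, t_takeoff, reason = "domain_exit")
  expect_false(endpoint_valid(exited, land_everywhere))
  fwd <- stub_trajectory(142.5, -10, t_takeoff, direction = "forward")
  expect_error(endpoint_valid(fwd, land_everywhere), "backward")
  # tolerance edge: 45 min off is acceptable, 90 min is not
  expect_true(endpoint_valid(stub_trajectory(142.5, -10, t_takeoff + 45 * 60),
                             land_everywhere))
  expect_false(endpoint_valid(stub_trajectory(142.5, -10, t_takeoff + 90 * 60),
                              land_everywhere))
})

test_that("the strict host tier narrows validity to the host region", {
  # host only on the western half
  lats <- seq(-12, -8, 0.5); lons <- seq(138, 146, 0.5)
  host <- outer(rep(TRUE, length(lats)), lons <= 142)
  mask <- land_mask(lats, lons, matrix(TRUE, length(lats), length(lons)), host = host)
  in_host <- stub_trajectory(140, -10, prev_local_clock_utc(t_takeoff, 140, 19))
  off_host <- stub_trajectory(145, -10, prev_local_clock_utc(t_takeoff + 86400, 145, 19))
  expect_true(endpoint_valid(in_host, mask, host_mode = "strict"))
  expect_false(endpoint_valid(off_host, mask, host_mode = "strict"))
  expect_true(endpoint_valid(off_host, mask, host_mode = "lenient"))
})

test_that("counting marks exactly the constructed valid paths", {
  trajs <- list(
    stub_trajectory(142.5, -10, t_takeoff, altitude = 500),            # valid
    stub_trajectory(143.5, -10.5, t_takeoff + 20 * 60, altitude = 750),  # valid
    stub_trajectory(142.5, -10, t_takeoff - 6 * 3600, altitude = 1000),  # wrong hour
    stub_trajectory(142.5, -10, t_takeoff - 5 * 3600, reason = "oversea_cap",
                    altitude = 1200),
    stub_trajectory(142.5, -10, t_takeoff, reason = "cold", altitude = 1500))
  paths <- stub_paths(trajs)
  rep <- filter_and_count(paths, land_everywhere)
  expect_equal(sum(rep$paths$valid), 2)
  expect_equal(rep$counts$n_valid[rep$counts$leg_index == 1], 2)
  expect_equal(rep$counts$n_candidates[rep$counts$leg_index == 1], 5)

  empty <- filter_and_count(stub_paths(list())[0, ], land_everywhere)
  expect_equal(nrow(empty$counts), 0)
  expect_equal(nrow(empty$endpoints), 0)

  # permutation invariance
  rep2 <- filter_and_count(stub_paths(trajs[c(3, 5, 1, 4, 2)]), land_everywhere)
  expect_equal(rep2$counts$n_valid, rep$counts$n_valid)
  expect_equal(sort(rep2$endpoints$end_lon), sort(rep$endpoints$end_lon))
})

test_that("validity is monotone in the land mask", {
  trajs <- list(stub_trajectory(142.5, -10, t_takeoff),
                stub_trajectory(144.5, -9, t_takeoff + 8 * 60))
  paths <- stub_paths(trajs)
  lats <- seq(-12, -8, 0.5); lons <- seq(138, 146, 0.5)
  small <- land_mask(lats, lons, outer(rep(TRUE, length(lats)), lons <= 143))
  big <- land_mask(lats, lons, matrix(TRUE, length(lats), length(lons)))
  n_small <- sum(filter_and_count(paths, small)$counts$n_valid)
  n_big <- sum(filter_and_count(paths, big)$counts$n_valid)
  expect_lte(n_small, n_big)
  expect_equal(n_small, 1)
  expect_equal(n_big, 2)
})

test_that("duration summaries use the sample standard deviation", {
  mk <- function(dur, lonoff) stub_trajectory(142.5 + lonoff, -10,
                                              t_takeoff + lonoff * 240,
                                              duration_h = dur)
  rep <- filter_and_count(stub_paths(list(mk(12, 0), mk(18, 0.05))), land_everywhere)
  s <- summarize_durations(rep, leg_index = 1)
  expect_equal(s$mean_h, 15)
  expect_equal(s$sd_h, sd(c(12, 18)))
  expect_equal(s$sd_h, 4.2426, tolerance = 1e-4)
  expect_false(s$degenerate)

  one <- filter_and_count(stub_paths(list(mk(30.5, 0))), land_everywhere)
  s1 <- summarize_durations(one, leg_index = 1)
  expect_equal(s1$mean_h, 30.5)
  expect_equal(s1$sd_h, 0)
  expect_true(s1$degenerate)

  same <- filter_and_count(stub_paths(list(mk(20, 0), mk(20, 0.02), mk(20, 0.04))),
                           land_everywhere)
  expect_equal(summarize_durations(same, 1)$sd_h, 0)
  none <- summarize_durations(rep, leg_index = 2)
  expect_equal(nrow(none), 0)
})

test_that("source regions summarise to centroid and hull", {
  sq <- list(stub_trajectory(142, -10, t_takeoff),
             stub_trajectory(144, -10, t_takeoff + 8 * 60),
             stub_trajectory(142, -8.5, t_takeoff + 16 * 60),
             stub_trajectory(144, -8.5, t_takeoff + 24 * 60))
  rep <- filter_and_count(stub_paths(sq), land_everywhere)
  s <- source_region_summary(rep)
  expect_equal(unname(s$centroid), c(143, -9.25))
  expect_equal(nrow(s$hull), 4)
  expect_false(s$degenerate)

  single <- filter_and_count(stub_paths(sq[1]), land_everywhere)
  s1 <- source_region_summary(single)
  expect_equal(unname(s1$centroid), c(142, -10))
  expect_true(s1$degenerate)
})

test_that("scenario recovery: valid endpoints sit on the truth source landmass", {
  sc <- scenario_2leg()
  rep <- report_2leg()
  first_leg <- dplyr::filter(rep$endpoints, leg_index == 2)
  expect_gt(nrow(first_leg), 0)
  d <- gc_km(cbind(first_leg$end_lon, first_leg$end_lat),
             c(sc$truth$source_lon, sc$truth$source_lat))
  expect_true(all(d < sc$truth$source_radius_km + 15))
  s <- source_region_summary(rep)
  expect_lt(gc_km(s$centroid, c(sc$truth$source_lon, sc$truth$source_lat)), 50)
})
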
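test_that("construction validates coordinates and shapes", {
  tm <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC") + c(0, 3600, 7200)
  good <- array(0, c(3, 2, 2, 2))
  expect_s3_class(met_field(tm, c(500, 1000), c(-10, -9), c(142, 143),
                            good, good, good), "met_field")
  expect_error(met_field(tm, c(500, 1000), c(-9, -9), c(142, 143), good, good, good),
               "monotone")
  expect_error(met_field(tm[1], c(500, 1000), c(-10, -9), c(142, 143),
                         array(0, c(1, 2, 2, 2)), array(0, c(1, 2, 2, 2)),
                         array(0, c(1, 2, 2, 2))), "two instants")
  expect_error(met_field(tm[c(1, 2, 2)] + c(0, 0, 1800), c(500, 1000), c(-10, -9),
                         c(142, 143), good, good, good), "regular")
  expect_error(met_field(tm, c(500, 1000), c(-10, -9), c(142, 143),
                         array(0, c(3, 2, 2, 3)), good, good), "dim")
})

test_that("pressure-level input converts to ascending heights in metres AGL", {
  tm <- as.POSIXct("2020-01-01", tz = "UTC") + c(0, 3600)
  a <- array(rep(c(1, 2), each = 2), c(2, 2, 1, 1))  # level 1 -> 1, level 2 -> 2
  fld <- met_field(tm, c(850, 900), -10, 142, a, a, a, level_kind = "pressure")
  expect_equal(fld$level_kind, "height_agl")
  expect_true(all(diff(fld$levels) > 0))
  expect_equal(fld$levels, height_from_pressure(c(900, 850)), tolerance = 1e-10)
  # the 900 hPa slice (value 2) must now be the lower level
  expect_equal(fld$u[1, 1, 1, 1], 2)
  expect_equal(fld$u[1, 2, 1, 1], 1)
})

test_that("NetCDF round trip preserves a synthetic field", {
  fld <- make_uniform_field(3, -2, 21, omega0 = 0.1, extent = c(140, 143, -11, -8),
                            duration_h = 5, res_deg = 1, levels = c(500, 1000, 1500))
  fld$u <- fld$u + array(stats::rnorm(length(fld$u), sd = 2), dim(fld$u))
  path <- withr::local_tempfile(fileext = ".nc")
  write_met_field(fld, path)
  back <- load_gridded_field(path)
  expect_equal(back$u, fld$u, tolerance = 1e-6)
  expect_equal(back$v, fld$v, tolerance = 1e-6)
  expect_equal(back$temperature, fld$temperature, tolerance = 1e-6)
  expect_equal(back$omega, fld$omega, tolerance = 1e-6)
  expect_equal(as.numeric(back$times), as.numeric(fld$times))
  expect_equal(back$levels, fld$levels)
})

test_that("Kelvin temperatures and variable maps are honoured on load", {
  path <- withr::local_tempfile(fileext = ".nc")
  dl <- ncdf4::ncdim_def("longitude", "degrees_east", c(142, 143))
  da <- ncdf4::ncdim_def("latitude", "degrees_north", c(-10, -9))
  dz <- ncdf4::ncdim_def("lev", "m", c(500, 1000))
  dt_ <- ncdf4::ncdim_def("time", "hours since 2020-01-01 00:00:00", 0:2)
  dims <- list(dl, da, dz, dt_)
  vars <- list(ncdf4::ncvar_def("U", "m s-1", dims, prec = "double"),
               ncdf4::ncvar_def("V", "m s-1", dims, prec = "double"),
               ncdf4::ncvar_def("T", "K", dims, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  arr <- array(288.15, c(2, 2, 2, 3))
  ncdf4::ncvar_put(nc, "U", arr * 0 + 1)
  ncdf4::ncvar_put(nc, "V", arr * 0)
  ncdf4::ncvar_put(nc, "T", arr)
  ncdf4::nc_close(nc)
  vm <- c(u = "U", v = "V", temperature = "T", time = "time",
          level = "lev", lat = "latitude", lon = "longitude")
  fld <- load_gridded_field(path, vm)
  s <- sample_atmosphere(fld, fld$times[1] + 1800, 142.5, -9.5, 750)
  expect_equal(s$temperature, 15.0, tolerance = 1e-9)
  expect_equal(as.numeric(fld$times[2] - fld$times[1], units = "hours"), 1)

  # missing variable is a named error
  vm_bad <- vm[names(vm) != "v"]
  expect_error(load_gridded_field(path, vm_bad), "`v`")
})

test_that("interpolation is exact at nodes and matches a brute-force oracle", {
  set.seed(11)
  tm <- as.POSIXct("2020-01-01", tz = "UTC") + (0:3) * 3600
  levels <- c(500, 1000, 2000)
  lats <- c(-11, -10, -9); lons <- c(141, 142, 143, 144)
  dims <- c(4, 3, 3, 4)
  fld <- met_field(tm, levels, lats, lons,
                   u = array(rnorm(prod(dims)), dims),
                   v = array(rnorm(prod(dims)), dims),
                   temperature = array(20 + rnorm(prod(dims)), dims),
                   omega = array(rnorm(prod(dims), sd = 0.1), dims))
  # node identity
  for (i in 1:4) {
    ti <- sample(4, 1); li <- sample(3, 1); ai <- sample(3, 1); oi <- sample(4, 1)
    s <- sample_atmosphere(fld, tm[ti], lons[oi], lats[ai], levels[li])
    expect_equal(s$u, fld$u[ti, li, ai, oi], tolerance = 1e-12)
    expect_equal(s$omega, fld$omega[ti, li, ai, oi], tolerance = 1e-12)
  }
  # brute-force cell-local quadrilinear oracle at random interior queries
  oracle <- function(arr, tq, lq, aq, oq) {
    w1 <- function(coord, x) {
      i <- max(which(coord <= x)); i <- min(i, length(coord) - 1)
      f <- (x - coord[i]) / (coord[i + 1] - coord[i])
      list(i = i, w = c(1 - f, f))
    }
    bt <- w1(as.numeric(tm), tq); bl <- w1(levels, lq)
    ba <- w1(lats, aq); bo <- w1(lons, oq)
    tot <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) for (d in 0:1) {
      tot <- tot + bt$w[a + 1] * bl$w[b + 1] * ba$w[cc + 1] * bo$w[d + 1] *
        arr[bt$i + a, bl$i + b, ba$i + cc, bo$i + d]
    }
    tot
  }
  for (i in 1:25) {
    tq <- as.numeric(tm[1]) + runif(1, 0, 3 * 3600)
    lq <- runif(1, 500, 2000); aq <- runif(1, -11, -9); oq <- runif(1, 141, 144)
    s <- sample_atmosphere(fld, as.POSIXct(tq, origin = "1970-01-01", tz = "UTC"),
                           oq, aq, lq)
    expect_equal(s$u, oracle(fld$u, tq, lq, aq, oq), tolerance = 1e-10)
    expect_equal(s$temperature, oracle(fld$temperature, tq, lq, aq, oq),
                 tolerance = 1e-10)
  }
  # out-of-domain is an explicit signal, not a clamp
  s_out <- sample_atmosphere(fld, tm[1], 150, -10, 1000)
  expect_false(s_out$in_domain)
  expect_true(is.na(s_out$u))
})

test_that("omega converts to vertical speed via the hydrostatic relation", {
  expect_equal(omega_to_vertical_ms(0, 85000, 288), 0)
  expect_equal(omega_to_vertical_ms(0.3, 85000, 288), -0.02975, tolerance = 1e-3)
  omega <- seq(-1, 1, 0.1)
  w <- omega_to_vertical_ms(omega, 85000, 288)
  expect_true(all(w[omega > 0] < 0))
  expect_equal(w, -rev(w))                    # odd in omega
  expect_true(all(diff(w) < 0))               # strictly decreasing
  expect_error(omega_to_vertical_ms(0.3, -1, 288), "pressure")
  expect_error(omega_to_vertical_ms(0.3, 85000, 0), "positive")
})

test_that("hypsometric heights behave like the 850 hPa ~ 1.5 km shorthand", {
  expect_equal(height_from_pressure(850), 1481, tolerance = 1e-3)
  expect_equal(height_from_pressure(1013.25), 0)
  expect_gt(height_from_pressure(800), height_from_pressure(850))
  expect_error(height_from_pressure(1100), "reference")
  # inverse consistency
  expect_equal(pressure_from_height(height_from_pressure(875)), 875, tolerance = 1e-9)
})
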
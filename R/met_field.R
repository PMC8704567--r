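# Gridded 4-D meteorological fields: container, validation, NetCDF I/O and
# space-time interpolation. Arrays are dimensioned [time, level, lat, lon];
# the canonical vertical coordinate is metres above ground level (AGL) and
# temperature is carried in degrees Celsius because the flight gate is stated
# in Celsius.

R_DRY <- 287.05      # specific gas constant of dry air, J/(kg K)
G_STD <- 9.80665     # standard gravity, m/s^2
EARTH_RADIUS_M <- 6371000
DEG_M <- EARTH_RADIUS_M * pi / 180  # metres per degree of great-circle arc

#' Construct a gridded meteorological field
#'
#' Builds and validates the 4-D atmosphere container used throughout the
#' package: zonal and meridional wind, air temperature and vertical pressure
#' velocity (omega) on a regular `time x level x lat x lon` grid. Pressure-level
#' inputs are converted to metres AGL at construction via the hypsometric
#' relation, so the trajectory engine only ever sees heights.
#'
#' @param times `POSIXct` (UTC), strictly increasing with a constant step;
#'   at least two instants.
#' @param levels Numeric vertical coordinate, strictly monotone. Interpreted
#'   according to `level_kind`.
#' @param lats,lons Strictly monotone coordinate vectors in degrees.
#' @param u,v Wind components (m/s), arrays of dim
#'   `c(length(times), length(levels), length(lats), length(lons))`.
#' @param temperature Air temperature, same shape. Celsius unless
#'   `temperature_unit = "K"`, in which case it is converted.
#' @param omega Vertical pressure velocity (Pa/s, positive = descending air),
#'   same shape. Defaults to zero.
#' @param rain Optional rain rate (mm/h), dim `time x lat x lon`. Carried for
#'   completeness; the trajectory engine does not use it.
#' @param level_kind `"height_agl"` (metres) or `"pressure"` (hPa). Pressure
#'   levels are converted to heights with [height_from_pressure()] using
#'   `mean_temperature`.
#' @param temperature_unit `"C"` or `"K"`.
#' @param mean_temperature Layer-mean temperature (K) used for the
#'   pressure-to-height conversion.
#' @return A `met_field` object.
#' @examples
#' fld <- make_uniform_field(u0 = 10, v0 = 0, T0 = 25)
#' sample_atmosphere(fld, fld$times[1] + 3600, lon = 142, lat = -9.5, alt = 1000)
#' @export
met_field <- function(times, levels, lats, lons, u, v, temperature,
                      omega = NULL, rain = NULL,
                      level_kind = c("height_agl", "pressure"),
                      temperature_unit = c("C", "K"),
                      mean_temperature = 288) {
  level_kind <- match.arg(level_kind)
  temperature_unit <- match.arg(temperature_unit)
  times <- as.POSIXct(times, tz = "UTC")
  if (length(times) < 2) stop("`times` must contain at least two instants", call. = FALSE)
  dt <- diff(as.numeric(times))
  if (any(dt <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-6 * dt[1]) {
    stop("`times` must have a regular step", call. = FALSE)
  }
  check_monotone <- function(x, name) {
    if (length(x) > 1 && !(all(diff(x) > 0) || all(diff(x) < 0))) {
      stop(sprintf("`%s` must be strictly monotone", name), call. = FALSE)
    }
  }
  check_monotone(levels, "levels")
  check_monotone(lats, "lats")
  check_monotone(lons, "lons")

  dims <- c(length(times), length(levels), length(lats), length(lons))
  check_shape <- function(x, name) {
    if (!identical(dim(x), as.integer(dims))) {
      stop(sprintf("`%s` must have dim time x level x lat x lon = [%s]",
                   name, paste(dims, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(omega)) omega <- array(0, dims)
  check_shape(u, "u"); check_shape(v, "v")
  check_shape(temperature, "temperature"); check_shape(omega, "omega")
  if (!is.null(rain) && !identical(dim(rain), as.integer(dims[c(1, 3, 4)]))) {
    stop("`rain` must have dim time x lat x lon", call. = FALSE)
  }
  if (temperature_unit == "K") temperature <- temperature - 273.15

  if (level_kind == "pressure") {
    heights <- height_from_pressure(levels, mean_temperature = mean_temperature)
    ord <- order(heights)
    levels <- heights[ord]
    reord <- function(a) a[, ord, , , drop = FALSE]
    u <- reord(u); v <- reord(v); temperature <- reord(temperature); omega <- reord(omega)
  }

  structure(
    list(times = times, levels = as.numeric(levels),
         lats = as.numeric(lats), lons = as.numeric(lons),
         u = u, v = v, temperature = temperature, omega = omega, rain = rain,
         level_kind = "height_agl"),
    class = "met_field"
  )
}

#' @export
print.met_field <- function(x, ...) {
  cat("<met_field>\n")
  cat(sprintf("  time : %s .. %s (%d steps of %s s)\n",
              format(x$times[1], "%Y-%m-%d %H:%M", tz = "UTC"),
              format(x$times[length(x$times)], "%Y-%m-%d %H:%M", tz = "UTC"),
              length(x$times), format(diff(as.numeric(x$times[1:2])))))
  cat(sprintf("  level: %g .. %g m AGL (%d)\n", min(x$levels), max(x$levels), length(x$levels)))
  cat(sprintf("  lat  : %g .. %g (%d)   lon: %g .. %g (%d)\n",
              min(x$lats), max(x$lats), length(x$lats),
              min(x$lons), max(x$lons), length(x$lons)))
  invisible(x)
}

# -- thermodynamic conversions ------------------------------------------------

#' Convert vertical pressure velocity to vertical speed
#'
#' Uses the hydrostatic relation `w = -omega / (rho g)` with the ideal-gas
#' density `rho = p / (R_d T)`. Positive omega (descending air) maps to
#' negative vertical speed.
#'
#' @param omega Vertical pressure velocity (Pa/s).
#' @param pressure Air pressure (Pa), > 0.
#' @param temperature Air temperature (K), > 0.
#' @return Vertical speed in m/s (positive upward).
#' @examples
#' omega_to_vertical_ms(0.3, pressure = 85000, temperature = 288)
#' @export
omega_to_vertical_ms <- function(omega, pressure, temperature) {
  if (any(pressure <= 0)) stop("`pressure` must be positive", call. = FALSE)
  if (any(temperature <= 0)) stop("`temperature` must be positive (Kelvin)", call. = FALSE)
  -omega * R_DRY * temperature / (pressure * G_STD)
}

#' Approximate height of a pressure level
#'
#' Hypsometric relation `z = (R_d T / g) log(p0 / p)` with a constant
#' layer-mean temperature; 850 hPa maps to roughly 1.5 km, matching the usual
#' shorthand for low-level-jet altitudes.
#'
#' @param pressure_hpa Pressure level (hPa), `0 < p <= reference`.
#' @param reference_pressure_hpa Surface reference pressure (hPa).
#' @param mean_temperature Layer-mean temperature (K).
#' @return Height in metres above the reference surface.
#' @examples
#' height_from_pressure(850)
#' @export
height_from_pressure <- function(pressure_hpa, reference_pressure_hpa = 1013.25,
                                 mean_temperature = 288) {
  if (any(pressure_hpa <= 0)) stop("`pressure_hpa` must be positive", call. = FALSE)
  if (any(pressure_hpa > reference_pressure_hpa)) {
    stop("`pressure_hpa` must not exceed the reference pressure", call. = FALSE)
  }
  (R_DRY * mean_temperature / G_STD) * log(reference_pressure_hpa / pressure_hpa)
}

#' Pressure of a height level (inverse hypsometric relation)
#'
#' @param height_m Height (m) above the reference surface.
#' @inheritParams height_from_pressure
#' @return Pressure in hPa.
#' @export
pressure_from_height <- function(height_m, reference_pressure_hpa = 1013.25,
                                 mean_temperature = 288) {
  reference_pressure_hpa * exp(-height_m * G_STD / (R_DRY * mean_temperature))
}

# -- interpolation ------------------------------------------------------------

# Bracketing index + fraction along a monotone coordinate. Queries outside the
# span get NA: out-of-domain sampling is an explicit signal (the trajectory
# engine records it as a domain exit), never a silent clamp.
.bracket <- function(coord, x) {
  n <- length(coord)
  desc <- n > 1 && coord[2] < coord[1]
  if (desc) {
    coord <- rev(coord)
    x_idx <- findInterval(x, coord, rightmost.closed = TRUE)
  } else {
    x_idx <- findInterval(x, coord, rightmost.closed = TRUE)
  }
  bad <- x_idx < 1L | x < coord[1] | x > coord[n]
  i <- pmin(pmax(x_idx, 1L), n - 1L)
  frac <- (x - coord[i]) / (coord[i + 1L] - coord[i])
  if (n == 1L) { i <- rep(1L, length(x)); frac <- rep(0, length(x)) }
  if (desc) {  # map back to original (descending) index space
    i_orig <- n - i       # original index of the upper bracket becomes lower
    list(i = i_orig, frac = 1 - frac, bad = bad)
  } else {
    list(i = i, frac = frac, bad = bad)
  }
}

#' Sample the atmosphere at points in space and time
#'
#' Quadrilinear interpolation of a [met_field()]: trilinear in
#' (level, lat, lon) and linear in time between the two bracketing frames.
#' All arguments are vectorised and recycled to a common length.
#'
#' @param field A `met_field`.
#' @param t Query times (`POSIXct`, UTC).
#' @param lon,lat Query position in degrees.
#' @param alt Query altitude in metres AGL.
#' @return A tibble with one row per query: `u`, `v`, `temperature`, `omega`
#'   and `in_domain`. Rows with any coordinate outside the grid span carry
#'   `in_domain = FALSE` and `NA` values.
#' @export
sample_atmosphere <- function(field, t, lon, lat, alt) {
  stopifnot(inherits(field, "met_field"))
  n <- max(length(t), length(lon), length(lat), length(alt))
  tt <- rep_len(as.numeric(as.POSIXct(t, tz = "UTC")), n)
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); alt <- rep_len(alt, n)

  bt <- .bracket(as.numeric(field$times), tt)
  bl <- .bracket(field$levels, alt)
  ba <- .bracket(field$lats, lat)
  bo <- .bracket(field$lons, lon)
  bad <- bt$bad | bl$bad | ba$bad | bo$bad

  d <- c(length(field$times), length(field$levels), length(field$lats), length(field$lons))
  # flattened index for [ti, li, ai, oi]
  flat <- function(ti, li, ai, oi) {
    ti + d[1] * ((li - 1L) + d[2] * ((ai - 1L) + d[3] * (oi - 1L)))
  }
  acc_u <- numeric(n); acc_v <- numeric(n); acc_T <- numeric(n); acc_w <- numeric(n)
  ti0 <- ifelse(bad, 1L, bt$i); li0 <- ifelse(bad, 1L, bl$i)
  ai0 <- ifelse(bad, 1L, ba$i); oi0 <- ifelse(bad, 1L, bo$i)
  ft <- bt$frac; fl <- bl$frac; fa <- ba$frac; fo <- bo$frac
  for (dt_ in 0:1) for (dl in 0:1) for (da in 0:1) for (do_ in 0:1) {
    w <- (if (dt_) ft else 1 - ft) * (if (dl) fl else 1 - fl) *
         (if (da) fa else 1 - fa) * (if (do_) fo else 1 - fo)
    idx <- flat(pmin(ti0 + dt_, d[1]), pmin(li0 + dl, d[2]),
                pmin(ai0 + da, d[3]), pmin(oi0 + do_, d[4]))
    acc_u <- acc_u + w * field$u[idx]
    acc_v <- acc_v + w * field$v[idx]
    acc_T <- acc_T + w * field$temperature[idx]
    acc_w <- acc_w + w * field$omega[idx]
  }
  acc_u[bad] <- NA_real_; acc_v[bad] <- NA_real_
  acc_T[bad] <- NA_real_; acc_w[bad] <- NA_real_
  tibble::tibble(u = acc_u, v = acc_v, temperature = acc_T, omega = acc_w,
                 in_domain = !bad)
}

# -- NetCDF I/O ---------------------------------------------------------------

#' Read a gridded meteorological field from NetCDF
#'
#' Expects CF-style 1-D coordinate variables and 4-D data variables ordered
#' `lon, lat, level, time` on disk (the layout [write_met_field()] produces and
#' the usual output of reanalysis post-processing). Temperatures in Kelvin
#' (detected from the variable's `units` attribute, or values > 150) are
#' converted to Celsius; pressure levels are converted to metres AGL.
#'
#' @param path Path to a NetCDF file.
#' @param variable_map Named character vector mapping the canonical names
#'   `u`, `v`, `temperature`, `omega` (optional), `rain` (optional) and the
#'   coordinates `time`, `level`, `lat`, `lon` to the file's variable names.
#'   Entries may be omitted where the file already uses the canonical name.
#' @param level_kind,mean_temperature Passed to [met_field()]; `level_kind`
#'   defaults to the file's `level_kind` global attribute, else height AGL.
#' @return A `met_field`.
#' @export
load_gridded_field <- function(path, variable_map = character(),
                               level_kind = NULL, mean_temperature = 288) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  name_of <- function(std) if (std %in% names(variable_map)) variable_map[[std]] else std
  have <- c(names(nc$var), names(nc$dim))
  need <- c("u", "v", "temperature")
  for (std in need) {
    if (!name_of(std) %in% names(nc$var)) {
      stop(sprintf("variable `%s` (mapped from `%s`) not found in %s",
                   name_of(std), std, path), call. = FALSE)
    }
  }
  get_coord <- function(std) {
    nm <- name_of(std)
    if (nm %in% names(nc$dim)) return(nc$dim[[nm]]$vals)
    if (nm %in% names(nc$var)) return(as.vector(ncdf4::ncvar_get(nc, nm)))
    stop(sprintf("coordinate `%s` (mapped from `%s`) not found", nm, std), call. = FALSE)
  }
  time_raw <- get_coord("time")
  tdim_name <- name_of("time")
  tunits <- tryCatch(ncdf4::ncatt_get(nc, tdim_name, "units")$value, error = function(e) NA)
  times <- .parse_nc_time(time_raw, tunits)
  levels <- get_coord("level")
  lats <- get_coord("lat"); lons <- get_coord("lon")

  get4 <- function(std) {
    a <- ncdf4::ncvar_get(nc, name_of(std), collapse_degen = FALSE)
    # disk order lon, lat, level, time -> internal time, level, lat, lon
    aperm(a, c(4, 3, 2, 1))
  }
  u <- get4("u"); v <- get4("v"); temp <- get4("temperature")
  omega <- if (name_of("omega") %in% names(nc$var)) get4("omega") else NULL
  rain <- if (name_of("rain") %in% names(nc$var)) {
    aperm(ncdf4::ncvar_get(nc, name_of("rain"), collapse_degen = FALSE), c(3, 2, 1))
  } else NULL

  tu <- tryCatch(ncdf4::ncatt_get(nc, name_of("temperature"), "units")$value,
                 error = function(e) NA)
  in_kelvin <- (is.character(tu) && grepl("^k", tolower(tu))) ||
    (!is.character(tu) && mean(temp, na.rm = TRUE) > 150)
  if (is.null(level_kind)) {
    lk <- ncdf4::ncatt_get(nc, 0, "level_kind")
    level_kind <- if (isTRUE(lk$hasatt)) lk$value else "height_agl"
  }
  met_field(times, levels, lats, lons, u, v, temp, omega = omega, rain = rain,
            level_kind = level_kind,
            temperature_unit = if (in_kelvin) "K" else "C",
            mean_temperature = mean_temperature)
}

.parse_nc_time <- function(vals, units) {
  if (is.character(units) && grepl("since", units)) {
    parts <- strsplit(units, "\\s+since\\s+")[[1]]
    mult <- switch(tolower(parts[1]),
                   seconds = 1, second = 1, hours = 3600, hour = 3600,
                   days = 86400, day = 86400, 1)
    origin <- as.POSIXct(parts[2], tz = "UTC",
                         tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
    origin + vals * mult
  } else {
    as.POSIXct(vals, origin = "1970-01-01", tz = "UTC")
  }
}

#' Write a gridded meteorological field to NetCDF
#'
#' Emits CF-style 1-D coordinates (`time`, `level`, `lat`, `lon`) and 4-D
#' variables in `lon, lat, level, time` disk order, so the file round-trips
#' through [load_gridded_field()].
#'
#' @param field A `met_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_met_field <- function(field, path) {
  stopifnot(inherits(field, "met_field"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lats)
  dim_lev <- ncdf4::ncdim_def("level", "m", field$levels)
  dim_time <- ncdf4::ncdim_def("time", "seconds since 1970-01-01 00:00:00",
                               as.numeric(field$times))
  dims4 <- list(dim_lon, dim_lat, dim_lev, dim_time)
  vars <- list(
    ncdf4::ncvar_def("u", "m s-1", dims4, prec = "double"),
    ncdf4::ncvar_def("v", "m s-1", dims4, prec = "double"),
    ncdf4::ncvar_def("temperature", "degC", dims4, prec = "double"),
    ncdf4::ncvar_def("omega", "Pa s-1", dims4, prec = "double")
  )
  if (!is.null(field$rain)) {
    vars <- c(vars, list(ncdf4::ncvar_def("rain", "mm h-1",
                                          list(dim_lon, dim_lat, dim_time),
                                          prec = "double")))
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  put4 <- function(name, a) ncdf4::ncvar_put(nc, name, aperm(a, c(4, 3, 2, 1)))
  put4("u", field$u); put4("v", field$v)
  put4("temperature", field$temperature); put4("omega", field$omega)
  if (!is.null(field$rain)) ncdf4::ncvar_put(nc, "rain", aperm(field$rain, c(3, 2, 1)))
  ncdf4::ncatt_put(nc, 0, "level_kind", field$level_kind)
  invisible(path)
}
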
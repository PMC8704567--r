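# Land/sea (and optional host-crop) masks on the met-field grid. The
# trajectory engine looks the surface up at every step (nearest cell), and the
# endpoint-validity filter distinguishes host regions from plain land.

#' Construct a land/sea mask
#'
#' A raster of surface type on a regular lat/lon grid, with an optional
#' host-crop raster used by the strict tier of the endpoint-validity filter.
#'
#' @param lats,lons Strictly monotone coordinate vectors (degrees).
#' @param land Logical matrix `lat x lon`; `TRUE` = land.
#' @param host Optional logical matrix of the same shape; `TRUE` = host
#'   planting region. Host cells must be land cells.
#' @return A `land_mask` object.
#' @export
land_mask <- function(lats, lons, land, host = NULL) {
  land <- matrix(as.logical(land), nrow = length(lats), ncol = length(lons))
  if (!is.null(host)) {
    host <- matrix(as.logical(host), nrow = length(lats), ncol = length(lons))
    if (any(host & !land)) stop("host cells must be land cells", call. = FALSE)
  }
  structure(list(lats = as.numeric(lats), lons = as.numeric(lons),
                 land = land, host = host),
            class = "land_mask")
}

#' @export
print.land_mask <- function(x, ...) {
  cat(sprintf("<land_mask> %d x %d cells, %.1f%% land%s\n",
              nrow(x$land), ncol(x$land), 100 * mean(x$land),
              if (is.null(x$host)) "" else sprintf(", %.1f%% host", 100 * mean(x$host))))
  invisible(x)
}

.nearest_idx <- function(coord, x) {
  i <- findInterval(x, coord + c(diff(coord) / 2, Inf)) + 1L
  pmin(pmax(i, 1L), length(coord))
}

#' Query surface type under a point
#'
#' Nearest-cell lookup, vectorised. Points outside the mask grid are treated
#' as sea (`is_land`) / non-host (`in_host`).
#'
#' @param mask A [land_mask()].
#' @param lon,lat Query coordinates (degrees).
#' @return Logical vector.
#' @export
is_land <- function(mask, lon, lat) {
  stopifnot(inherits(mask, "land_mask"))
  inside <- lat >= min(mask$lats) & lat <= max(mask$lats) &
    lon >= min(mask$lons) & lon <= max(mask$lons)
  la <- .nearest_idx(mask$lats, lat)
  lo <- .nearest_idx(mask$lons, lon)
  out <- mask$land[cbind(la, lo)]
  out & inside
}

#' @rdname is_land
#' @export
in_host <- function(mask, lon, lat) {
  stopifnot(inherits(mask, "land_mask"))
  if (is.null(mask$host)) return(rep(FALSE, max(length(lon), length(lat))))
  inside <- lat >= min(mask$lats) & lat <= max(mask$lats) &
    lon >= min(mask$lons) & lon <= max(mask$lons)
  la <- .nearest_idx(mask$lats, lat)
  lo <- .nearest_idx(mask$lons, lon)
  mask$host[cbind(la, lo)] & inside
}

#' Synthetic masks: uniform and island geometries
#'
#' `mask_uniform()` makes an all-land or all-sea mask on a grid;
#' `mask_islands()` rasterises circular islands (given centre and radius in
#' km, great-circle distance) onto the grid, optionally flagging some islands
#' as host regions.
#'
#' @param lats,lons Grid coordinate vectors (degrees).
#' @param land Single logical: `TRUE` for all-land.
#' @param islands A data frame with columns `lon`, `lat`, `radius_km` and
#'   optionally logical `host`.
#' @return A [land_mask()].
#' @export
mask_uniform <- function(lats, lons, land = TRUE) {
  land_mask(lats, lons, matrix(land, length(lats), length(lons)))
}

#' @rdname mask_uniform
#' @export
mask_islands <- function(lats, lons, islands) {
  stopifnot(all(c("lon", "lat", "radius_km") %in% names(islands)))
  grid <- expand.grid(lat = lats, lon = lons)  # lat varies fastest = column-major
  land <- matrix(FALSE, length(lats), length(lons))
  host <- matrix(FALSE, length(lats), length(lons))
  any_host <- FALSE
  for (k in seq_len(nrow(islands))) {
    d <- geosphere::distGeo(cbind(grid$lon, grid$lat),
                            c(islands$lon[k], islands$lat[k])) / 1000
    inside <- matrix(d <= islands$radius_km[k], length(lats), length(lons))
    land <- land | inside
    if (isTRUE(islands$host[k])) { host <- host | inside; any_host <- TRUE }
  }
  land_mask(lats, lons, land, host = if (any_host) host else NULL)
}

#' Read / write a land mask as NetCDF
#'
#' Masks are stored as byte rasters (`land`, optional `host`) with 1-D `lat`
#' and `lon` coordinates.
#'
#' @param mask A [land_mask()].
#' @param path File path.
#' @return `write_land_mask()` returns `path` invisibly; `load_land_mask()`
#'   returns a [land_mask()].
#' @export
write_land_mask <- function(mask, path) {
  stopifnot(inherits(mask, "land_mask"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", mask$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", mask$lats)
  vars <- list(ncdf4::ncvar_def("land", "1", list(dim_lon, dim_lat), prec = "byte"))
  if (!is.null(mask$host)) {
    vars <- c(vars, list(ncdf4::ncvar_def("host", "1", list(dim_lon, dim_lat), prec = "byte")))
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, "land", t(mask$land * 1L))
  if (!is.null(mask$host)) ncdf4::ncvar_put(nc, "host", t(mask$host * 1L))
  invisible(path)
}

#' @rdname write_land_mask
#' @export
load_land_mask <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  lats <- nc$dim$lat$vals
  lons <- nc$dim$lon$vals
  land <- t(ncdf4::ncvar_get(nc, "land", collapse_degen = FALSE)) > 0
  host <- if ("host" %in% names(nc$var)) {
    t(ncdf4::ncvar_get(nc, "host", collapse_degen = FALSE)) > 0
  } else NULL
  land_mask(lats, lons, land, host = host)
}
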
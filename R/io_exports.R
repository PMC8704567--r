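# Tabular and GeoJSON exports of candidate paths.

#' Export candidate paths as CSV
#'
#' One row per trajectory point across all paths and legs: `path_id`,
#' `leg_index`, time, position, altitude, wind, temperature and surface.
#'
#' @param paths A `multileg_paths` tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_paths_csv <- function(paths, file) {
  pts <- purrr::map_dfr(seq_len(nrow(paths)), function(i) {
    dplyr::bind_rows(purrr::map(paths$legs[[i]], function(tr) {
      dplyr::mutate(tr$points, leg_index = tr$leg_index)
    })) |>
      dplyr::mutate(path_id = paths$path_id[i], .before = 1)
  })
  pts$time <- format(pts$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(pts, file, row.names = FALSE)
  invisible(file)
}

#' Export candidate paths as GeoJSON
#'
#' A FeatureCollection with one LineString per leg, carrying `path_id`,
#' `leg_index`, `termination_reason`, `duration_h` and (when present)
#' `valid` as properties.
#'
#' @inheritParams write_paths_csv
#' @return `file`, invisibly.
#' @export
write_paths_geojson <- function(paths, file) {
  features <- purrr::flatten(purrr::map(seq_len(nrow(paths)), function(i) {
    purrr::map(paths$legs[[i]], function(tr) {
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = cbind(tr$points$lon, tr$points$lat)),
           properties = list(path_id = paths$path_id[i],
                             leg_index = tr$leg_index,
                             termination_reason = tr$termination_reason,
                             duration_h = tr$flight_duration_h,
                             valid = if ("valid" %in% names(paths)) paths$valid[i]))
    })
  }))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file, auto_unbox = TRUE, digits = 6, null = "null")
  invisible(file)
}

#' Export valid endpoints as GeoJSON points
#'
#' @param report A `validity_report` from [filter_and_count()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_endpoints_geojson <- function(report, file) {
  stopifnot(inherits(report, "validity_report"))
  ep <- report$endpoints
  features <- purrr::map(seq_len(nrow(ep)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(ep$end_lon[i], ep$end_lat[i])),
         properties = list(leg_index = ep$leg_index[i],
                           end_time = format(ep$end_time[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                           duration_h = ep$duration_h[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file, auto_unbox = TRUE, digits = 6)
  invisible(file)
}
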
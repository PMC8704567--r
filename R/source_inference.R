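# Endpoint-validity filtering of backward trajectories, per-migration counts,
# flight-duration statistics and source-region summaries.

#' Is a backward-trajectory endpoint a valid take-off?
#'
#' A backward leg's endpoint is accepted as a plausible departure when it
#' (a) lies on land -- in the strict tier, inside the host planting region --
#' (b) falls within the take-off tolerance of the local dusk take-off time,
#' and (c) the leg did not terminate through the cold gate or by leaving the
#' grid.
#'
#' @param traj A backward `trajectory` from [run_leg()].
#' @param mask A [land_mask()].
#' @param params A [flight_params()].
#' @param host_mode `"lenient"` (any terrestrial endpoint, the default: the
#'   filter accepts a host region *or at least* land) or `"strict"` (endpoint
#'   must be inside the mask's host region).
#' @return Logical scalar.
#' @export
endpoint_valid <- function(traj, mask, params = flight_params(),
                           host_mode = c("lenient", "strict")) {
  host_mode <- match.arg(host_mode)
  stopifnot(inherits(traj, "trajectory"))
  if (traj$direction != "backward") {
    stop("endpoint validity is defined for backward trajectories", call. = FALSE)
  }
  if (traj$termination_reason %in% c("cold", "domain_exit")) return(FALSE)
  ep <- traj$points[nrow(traj$points), ]
  on_land <- is_land(mask, ep$lon, ep$lat)
  ok_surface <- if (host_mode == "strict" && !is.null(mask$host)) {
    in_host(mask, ep$lon, ep$lat)
  } else {
    on_land
  }
  if (!isTRUE(ok_surface)) return(FALSE)
  h <- local_solar_hour(ep$time, ep$lon)
  dh <- min(abs(h - params$takeoff_local), 24 - abs(h - params$takeoff_local))
  dh <= params$takeoff_tolerance_h
}

#' Filter candidate paths and count valid trajectories per migration
#'
#' Marks every candidate path valid or invalid by applying
#' [endpoint_valid()] to its final (earliest-in-time) leg, then counts the
#' distinct trajectories per leg passing validity. Legs nearest arrival
#' (leg index 1) are the chronologically *second* migration; preceding legs
#' the *first*, matching the convention that the earlier flight is named
#' first.
#'
#' @param paths A `multileg_paths` tibble from [run_multileg_backward()].
#' @param mask A [land_mask()].
#' @param params A [flight_params()].
#' @param host_mode Passed to [endpoint_valid()].
#' @return A `validity_report`: a list with `paths` (the input with a `valid`
#'   column), `counts` (per-leg distinct valid trajectories), `durations`
#'   (per-leg mean, sample SD and SE of flight hours over valid legs) and
#'   `endpoints` (coordinates of valid final endpoints).
#' @export
filter_and_count <- function(paths, mask, params = flight_params(),
                             host_mode = c("lenient", "strict")) {
  host_mode <- match.arg(host_mode)
  if (nrow(paths) == 0) {
    empty_counts <- tibble::tibble(leg_index = integer(), migration = character(),
                                   n_valid = integer())
    return(structure(list(paths = paths, counts = empty_counts,
                          durations = tibble::tibble(), endpoints = tibble::tibble()),
                     class = "validity_report"))
  }
  paths$valid <- purrr::map_lgl(paths$legs, function(legs) {
    endpoint_valid(legs[[length(legs)]], mask, params, host_mode)
  })

  # one record per distinct trajectory per leg (a trajectory is identified by
  # its release hour, altitude and, for chained legs, its stopover cell)
  leg_records <- purrr::map_dfr(seq_len(nrow(paths)), function(i) {
    legs <- paths$legs[[i]]
    n <- length(legs)
    purrr::map_dfr(seq_along(legs), function(j) {
      tr <- legs[[j]]
      ep <- tr$points[nrow(tr$points), ]
      tibble::tibble(
        leg_index = tr$leg_index,
        traj_id = paste(tr$leg_index,
                        if (tr$leg_index == 1L) "" else paths$stopover_cell[i],
                        tr$release$time, tr$release$altitude_m, sep = "|"),
        duration_h = tr$flight_duration_h,
        end_lon = ep$lon, end_lat = ep$lat, end_time = ep$time,
        # a leg counts as valid when it is the final leg of a valid path
        valid = j == n && paths$valid[i])
    })
  })
  leg_records <- dplyr::summarise(
    dplyr::group_by(leg_records, leg_index, traj_id),
    duration_h = duration_h[1], end_lon = end_lon[1], end_lat = end_lat[1],
    end_time = end_time[1], valid = any(valid), .groups = "drop")

  migration_name <- function(leg_index) ifelse(leg_index == 1L, "second", "first")
  counts <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(leg_records, leg_index),
    migration = migration_name(leg_index[1]),
    n_candidates = dplyr::n(),
    n_valid = sum(valid), .groups = "drop"), dplyr::desc(leg_index))

  valid_legs <- dplyr::filter(leg_records, valid)
  durations <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(valid_legs, leg_index),
    migration = migration_name(leg_index[1]),
    n = dplyr::n(),
    mean_h = mean(duration_h),
    sd_h = if (dplyr::n() > 1) stats::sd(duration_h) else 0,
    se_h = if (dplyr::n() > 1) stats::sd(duration_h) / sqrt(dplyr::n()) else 0,
    degenerate = dplyr::n() < 2, .groups = "drop"), dplyr::desc(leg_index))

  endpoints <- dplyr::select(valid_legs, leg_index, traj_id,
                             end_lon, end_lat, end_time, duration_h)
  structure(list(paths = paths, counts = counts, durations = durations,
                 endpoints = endpoints),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report>\n")
  if (nrow(x$counts) == 0) { cat("  no candidate paths\n"); return(invisible(x)) }
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %s migration (leg %d): %d valid of %d candidates\n",
                x$counts$migration[i], x$counts$leg_index[i],
                x$counts$n_valid[i], x$counts$n_candidates[i]))
  }
  for (i in seq_len(nrow(x$durations))) {
    cat(sprintf("  %s migration duration: %.2f +/- %.2f h (n = %d)\n",
                x$durations$migration[i], x$durations$mean_h[i],
                x$durations$sd_h[i], x$durations$n[i]))
  }
  invisible(x)
}

#' Flight-duration summary for one leg
#'
#' Arithmetic mean and sample (n - 1) standard deviation of flight duration
#' over the valid trajectories of one leg of a filtered path set.
#'
#' @param report A `validity_report` from [filter_and_count()], or a
#'   `multileg_paths` tibble (then `mask`/`params` are required to filter).
#' @param leg_index Which leg (1 = nearest arrival).
#' @param mask,params Used only when `report` is an unfiltered path set.
#' @return A one-row tibble with `n`, `mean_h`, `sd_h`, `se_h` and
#'   `degenerate` (`TRUE` when fewer than two durations; `sd_h` is then 0 by
#'   convention). Zero valid legs gives a zero-row tibble.
#' @export
summarize_durations <- function(report, leg_index = 1L, mask = NULL,
                                params = flight_params()) {
  if (!inherits(report, "validity_report")) {
    report <- filter_and_count(report, mask, params)
  }
  dplyr::select(dplyr::filter(report$durations, .data$leg_index == !!leg_index),
                n, mean_h, sd_h, se_h, degenerate)
}

#' Summarise the inferred source region
#'
#' Unweighted centroid and convex hull of the valid final endpoints of a
#' filtered path set.
#'
#' @param report A `validity_report` from [filter_and_count()].
#' @return A list with `centroid` (named lon/lat), `hull` (tibble of hull
#'   vertices in order), `n_endpoints` and `degenerate` (`TRUE` when fewer
#'   than three distinct endpoints, so the hull collapses to a point or
#'   segment).
#' @export
source_region_summary <- function(report) {
  stopifnot(inherits(report, "validity_report"))
  # endpoints of the deepest leg of each valid path (the inferred departures)
  ep <- report$endpoints
  if (nrow(ep) == 0) stop("no valid endpoints to summarise", call. = FALSE)
  deepest <- max(ep$leg_index)
  ep <- dplyr::filter(ep, .data$leg_index == deepest)
  centroid <- c(lon = mean(ep$end_lon), lat = mean(ep$end_lat))
  pts <- unique(cbind(ep$end_lon, ep$end_lat))
  degenerate <- nrow(pts) < 3
  hull_idx <- if (degenerate) seq_len(nrow(pts)) else grDevices::chull(pts)
  list(centroid = centroid,
       hull = tibble::tibble(lon = pts[hull_idx, 1], lat = pts[hull_idx, 2]),
       n_endpoints = nrow(ep), degenerate = degenerate)
}
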
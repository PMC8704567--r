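# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into its point table
#'
#' @param x A `trajectory` from [run_leg()].
#' @param ... Unused.
#' @return A tibble with one row per trajectory point (`time`, `lon`, `lat`,
#'   `altitude_m`, wind, temperature, surface) plus `leg_index` and
#'   `direction`.
#' @export
tidy.trajectory <- function(x, ...) {
  dplyr::mutate(x$points, leg_index = x$leg_index, direction = x$direction)
}

#' @rdname tidy.trajectory
#' @export
glance.trajectory <- function(x, ...) {
  ep <- x$points[nrow(x$points), ]
  tibble::tibble(direction = x$direction, leg_index = x$leg_index,
                 termination_reason = x$termination_reason,
                 flight_duration_h = x$flight_duration_h,
                 n_points = nrow(x$points),
                 release_time = x$points$time[1],
                 end_time = ep$time, end_lon = ep$lon, end_lat = ep$lat,
                 end_surface = ep$surface)
}

#' Tidy a validity report
#'
#' @param x A `validity_report` from [filter_and_count()].
#' @param ... Unused.
#' @return `tidy()`: the per-leg counts and duration statistics joined into
#'   one tibble. `glance()`: a one-row overview.
#' @export
tidy.validity_report <- function(x, ...) {
  dplyr::left_join(x$counts,
                   dplyr::select(x$durations, leg_index, n, mean_h, sd_h, se_h),
                   by = "leg_index")
}

#' @rdname tidy.validity_report
#' @export
glance.validity_report <- function(x, ...) {
  tibble::tibble(n_paths = nrow(x$paths),
                 n_valid_paths = sum(x$paths$valid %||% logical()),
                 n_valid_trajectories = sum(x$counts$n_valid),
                 n_legs = nrow(x$counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
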
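# ggplot2 displays for the climatology and trajectory products.

#' Plot a wind rose
#'
#' Circular histogram of the sixteen 22.5-degree sectors; bar height is the
#' sector frequency, fill the per-sector mean wind speed.
#'
#' @param object A `wind_rose` from [monthly_wind_rose()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wind_rose <- function(object, ...) {
  df <- dplyr::mutate(object, angle = sector * 22.5)
  ggplot2::ggplot(df, ggplot2::aes(x = angle, y = frequency, fill = mean_speed)) +
    ggplot2::geom_col(width = 22.5, colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = -11.25 * pi / 180) +
    ggplot2::scale_x_continuous(breaks = seq(0, 337.5, 22.5), limits = c(-11.25, 348.75),
                                labels = SECTOR_NAMES) +
    ggplot2::scale_fill_viridis_c(name = "mean speed (m/s)") +
    ggplot2::labs(x = NULL, y = "frequency",
                  title = sprintf("Nocturnal wind rose, month %s", attr(object, "month"))) +
    ggplot2::theme_minimal()
}

#' Plot a time-height omega profile
#'
#' @param object A `vv_profile` from [vertical_velocity_profile()].
#' @param ... Unused.
#' @return A ggplot object; positive omega (descending air) plots red.
#' @export
autoplot.vv_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = time, y = level_hpa, fill = omega)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "omega (Pa/s)") +
    ggplot2::labs(x = NULL, y = "pressure level (hPa)") +
    ggplot2::theme_minimal()
}

#' Map candidate backward paths over the land mask
#'
#' @param paths A `multileg_paths` tibble (optionally filtered: if it carries
#'   a `valid` column, valid paths are emphasised).
#' @param mask Optional [land_mask()] drawn as the base layer.
#' @return A ggplot object.
#' @export
plot_paths <- function(paths, mask = NULL) {
  pts <- purrr::map_dfr(seq_len(nrow(paths)), function(i) {
    dplyr::bind_rows(purrr::map(paths$legs[[i]], ~ tidy(.x))) |>
      dplyr::mutate(path_id = paths$path_id[i],
                    valid = if ("valid" %in% names(paths)) paths$valid[i] else NA)
  })
  p <- ggplot2::ggplot()
  if (!is.null(mask)) {
    land_df <- tidyr::expand_grid(lon = mask$lons, lat = mask$lats)
    land_df$land <- as.vector(mask$land)  # column-major: lat varies fastest
    p <- p + ggplot2::geom_raster(data = dplyr::filter(land_df, land),
                                  ggplot2::aes(x = lon, y = lat), fill = "grey80")
  }
  p +
    ggplot2::geom_path(data = pts,
                       ggplot2::aes(x = lon, y = lat, group = interaction(path_id, leg_index),
                                    colour = factor(leg_index), alpha = valid)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.15), na.value = 0.5,
                                guide = "none") +
    ggplot2::labs(colour = "leg", x = "longitude", y = "latitude") +
    ggplot2::coord_quickmap() +
    ggplot2::theme_minimal()
}
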
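raster_df <- function(mat, value_name = "value") {
  tibble(col = as.vector(col(mat)), row = as.vector(row(mat)),
         value = as.vector(mat)) |>
    stats::setNames(c("col", "row", value_name))
}

#' Plot an NDVI raster
#'
#' @param object an `ndvi_raster` from [compute_ndvi()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ndvi_raster <- function(object, ...) {
  df <- raster_df(object$values, "ndvi")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$ndvi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "sienna", mid = "khaki",
                                  high = "darkgreen", midpoint = 0.1,
                                  limits = c(-1, 1), na.value = "grey70") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "NDVI")
}

#' Plot a vegetation mask
#'
#' @param object a `veg_mask` from [classify_vegetation()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.veg_mask <- function(object, ...) {
  df <- raster_df(object$mask, "vegetation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$vegetation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "wheat",
                                          `TRUE` = "darkgreen")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "vegetation")
}

#' Plot survey densities by year
#'
#' @param object a `survey_density` tibble from [survey_density()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.survey_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$year),
                                       y = .data$density_per_100m2)) +
    ggplot2::geom_col(fill = "darkgreen", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$density_1dp)),
                       vjust = -0.4) +
    ggplot2::labs(x = "survey year", y = "plants per 100 m²")
}

#' Overlay detected plants on an aerial scene
#'
#' Renders the first band as a grey background with detected object
#' centroids marked and circles of equivalent canopy area.
#'
#' @param scene the [aerial_scene()] that was analysed.
#' @param objects detected objects from [detect_plants()].
#' @return a ggplot.
#' @export
plot_detections <- function(scene, objects) {
  ps <- scene$pixel_size
  df <- raster_df(scene$bands[, , 1], "reflectance")
  df$x <- (df$col - 0.5) * ps
  df$y <- (df$row - 0.5) * ps
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$reflectance)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "m", y = "m")
  if (nrow(objects) > 0) {
    obj <- as_tibble(objects[c("centroid_x", "centroid_y", "area_m2")])
    p <- p +
      ggplot2::geom_point(data = obj,
                          ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y),
                          colour = "red", shape = 3, size = 2) +
      ggplot2::geom_point(data = obj,
                          ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y,
                                       size = .data$area_m2),
                          colour = "red", shape = 1) +
      ggplot2::scale_size_area(name = "canopy m²")
  }
  p
}
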
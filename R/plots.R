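#' @name plots
#' @title ggplot2 views of meshes, fields, sweeps and lesions
NULL

mesh_triangles_df <- function(mesh, value = NULL) {
  tri <- mesh$tri
  df <- tibble(
    id = rep(seq_len(nrow(tri)), each = 3),
    r = as.vector(t(cbind(
      mesh$nodes[tri[, 1], 1], mesh$nodes[tri[, 2], 1], mesh$nodes[tri[, 3], 1]
    ))) * 1e3,
    z = as.vector(t(cbind(
      mesh$nodes[tri[, 1], 2], mesh$nodes[tri[, 2], 2], mesh$nodes[tri[, 3], 2]
    ))) * 1e3,
    region = rep(mesh$region %||% "domain", each = 3)
  )
  if (!is.null(value)) df$value <- rep(value, each = 3)
  df
}

#' @export
autoplot.abl_mesh <- function(object, ...) {
  df <- mesh_triangles_df(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$z, group = .data$id, fill = .data$region)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.05) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (mm)", y = "z (mm)", fill = "region")
}

#' @export
autoplot.abl_sar <- function(object, ...) {
  df <- mesh_triangles_df(object$mesh, value = log10(pmax(object$sar, 1e-3)))
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$z, group = .data$id, fill = .data$value)) +
    ggplot2::geom_polygon() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (mm)", y = "z (mm)", fill = "log10 SAR (W/kg)")
}

#' @export
autoplot.abl_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency / 1e9, .data$swr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "frequency (GHz)", y = "SWR")
}

#' @export
autoplot.abl_temp_series <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$T_max)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "maximum temperature (°C)")
}

#' @export
autoplot.abl_isotherm <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$r1, y = .data$z1, xend = .data$r2, yend = .data$z2
    )) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "r (mm)", y = "z (mm)",
      title = sprintf("%g °C isotherm", attr(object, "level"))
    )
}

#' Temperature field snapshot plot
#'
#' @param run An `abl_run`.
#' @param at_time Snapshot time (s); defaults to the final one.
#' @return A ggplot object.
#' @export
plot_temperature_field <- function(run, at_time = max(run$series$times)) {
  Tn <- series_at_time(run$series, at_time)
  tri <- run$mesh$tri
  val <- (Tn[tri[, 1]] + Tn[tri[, 2]] + Tn[tri[, 3]]) / 3
  df <- mesh_triangles_df(run$mesh, value = val)
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$z, group = .data$id, fill = .data$value)) +
    ggplot2::geom_polygon() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "r (mm)", y = "z (mm)",
      fill = sprintf("T (°C) at %g s", at_time)
    )
}
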
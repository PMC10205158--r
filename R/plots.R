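#' Plot axial slices of a volume
#'
#' Shared slice plotting for correlation (`rsa_map`) and statistic (`t_map`)
#' volumes.
#'
#' @param vol 3D numeric array.
#' @param slices z indices to show (default: 4 evenly spaced in-data slices).
#' @param value_name legend title.
#' @return a ggplot object.
#' @export
plot_volume_slices <- function(vol, slices = NULL, value_name = "value") {
  d <- dim(vol)
  if (is.null(slices)) {
    zs <- which(apply(vol, 3L, function(s) any(is.finite(s))))
    if (!length(zs)) zs <- seq_len(d[3L])
    slices <- unique(round(stats::quantile(zs, c(0.2, 0.4, 0.6, 0.8))))
  }
  df <- purrr::map_dfr(slices, function(z) {
    tibble(x = rep(seq_len(d[1L]), d[2L]),
           y = rep(seq_len(d[2L]), each = d[1L]),
           value = as.numeric(vol[, , z]), slice = z)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(name = value_name, na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.rsa_map <- function(object, slices = NULL, ...) {
  plot_volume_slices(unclass(object), slices,
                     value_name = attr(object, "statistic") %||% "rho")
}

#' @exportS3Method ggplot2::autoplot
autoplot.t_map <- function(object, slices = NULL, ...) {
  plot_volume_slices(unclass(object), slices, value_name = "t")
}
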
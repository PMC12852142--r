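#' Plot a raster surface with ggplot2
#'
#' @param surface numeric matrix (row 1 is drawn at the top).
#' @param name legend title.
#' @return A ggplot object.
#' @examples
#' stack <- make_single_patch(scenario_spec("single_patch_low_contrast"))
#' plot_surface(stack$membership[, , 1], "membership")
#' @export
plot_surface <- function(surface, name = "value") {
  stopifnot(is.matrix(surface))
  df <- tibble::tibble(
    row = rep(seq_len(nrow(surface)), ncol(surface)),
    col = rep(seq_len(ncol(surface)), each = nrow(surface)),
    value = as.vector(surface))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @method autoplot class_stack
#' @export
autoplot.class_stack <- function(object, what = c("membership", "variance"),
                                 ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  df$value <- df[[what]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~class) +
    ggplot2::theme_minimal()
}

#' @method autoplot patch_set
#' @export
autoplot.patch_set <- function(object, ...) {
  lab <- object$labels
  df <- tibble::tibble(
    row = rep(seq_len(nrow(lab)), ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    patch = as.vector(lab))
  df$patch <- ifelse(df$patch == 0L, NA_character_, as.character(df$patch))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$patch)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "patch") +
    ggplot2::theme_minimal()
}
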
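#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

need_ggplot <- function() invisible(TRUE)

raster_df <- function(m) {
  data.frame(row = as.vector(row(m)), col = as.vector(col(m)),
             value = as.vector(m))
}

#' Plot one channel of a flat-mount image
#'
#' @param object a [flatmount_image].
#' @param channel channel name (default: first).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.flatmount_image <- function(object, channel = names(object$channels)[1], ...) {
  need_ggplot()
  df <- raster_df(object$channels[[channel]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = channel, fill = "intensity",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a skeleton coloured by component
#'
#' @param object a `skeleton_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.skeleton_graph <- function(object, ...) {
  need_ggplot()
  idx <- which(object$pixels)
  df <- data.frame(row = (idx - 1) %% nrow(object$pixels) + 1,
                   col = (idx - 1) %/% nrow(object$pixels) + 1,
                   component = factor(object$labels[idx]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   colour = .data$component)) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a 4PL standard curve with its standards
#'
#' @param object a `fourpl_fit`.
#' @param n_points curve resolution.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fourpl_fit <- function(object, n_points = 200, ...) {
  need_ggplot()
  xs <- exp(seq(log(max(object$range[1], object$c / 100)),
                log(max(object$range[2], object$c * 100)),
                length.out = n_points))
  curve <- data.frame(concentration = xs, response = predict(object, xs))
  pts <- eval(object$fit$data)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$concentration,
                                      y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = as.data.frame(pts)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "response") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
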
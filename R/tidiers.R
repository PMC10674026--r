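#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training log of a fit
#'
#' @param x A `retseg_fit`.
#' @param ... Unused.
#' @return Tibble with one row per optimisation step (`step`, `epoch`,
#'   `total`, `final_term`).
#' @exportS3Method generics::tidy
tidy.retseg_fit <- function(x, ...) x$log

#' One-row summary of a fit
#'
#' @param x A `retseg_fit`.
#' @param ... Unused.
#' @return Tibble with step count, initial/final loss and their ratio.
#' @exportS3Method generics::glance
glance.retseg_fit <- function(x, ...) {
  tibble::tibble(steps = nrow(x$log),
                 initial_loss = x$log$total[1],
                 final_loss = utils::tail(x$log$total, 1),
                 loss_ratio = utils::tail(x$log$total, 1) / x$log$total[1])
}

#' Per-image metrics of an evaluation
#'
#' @param x A `retseg_eval`.
#' @param ... Unused.
#' @return The per-image metrics tibble.
#' @exportS3Method generics::tidy
tidy.retseg_eval <- function(x, ...) x$per_image

#' @rdname tidy.retseg_eval
#' @exportS3Method generics::glance
glance.retseg_eval <- function(x, ...) x$aggregate

#' Training-loss curve
#'
#' @param object A `retseg_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.retseg_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$step, y = .data$total)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "optimisation step", y = "composite loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Display a fundus sample as an image panel
#'
#' @param object A `fundus_sample`.
#' @param layer `"image"` (green channel), `"vessel"` or `"fov"`.
#' @param ... Unused.
#' @return A ggplot raster.
#' @exportS3Method ggplot2::autoplot
autoplot.fundus_sample <- function(object,
                                   layer = c("image", "vessel", "fov"), ...) {
  layer <- match.arg(layer)
  m <- switch(layer,
              image = object$image[, , 2],
              vessel = object$vessel_mask,
              fov = object$fov_mask)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("fundus phantom:", layer)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
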
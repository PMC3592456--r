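# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chi-square surface
#'
#' Raster display of the averaged reduced chi-square over the two scanned
#' parameters; the grid minimum is marked. Rejected (constraint-violating)
#' points are left blank and excluded from the color scale.
#'
#' @param object A `fret_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fret_surface <- function(object, ...) {
  df <- tidy.fret_surface(object)
  p1 <- rlang::sym(object$parameters[1])
  p2 <- rlang::sym(object$parameters[2])
  ggplot2::ggplot(df, ggplot2::aes(!!p1, !!p2, fill = .data$chi2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::annotate("point", x = object$minimum[1], y = object$minimum[2],
                      shape = 4, size = 3, colour = "white") +
    ggplot2::labs(fill = expression(chi[r]^2)) +
    ggplot2::theme_minimal()
}

#' Plot measured decays with their fitted model curves
#'
#' Log-scale overlay of the measured counts and the model reconvolution for
#' each curve of a fitted dataset.
#'
#' @param object A `fret_fit`.
#' @param curves Optional integer subset of curve indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fret_fit <- function(object, curves = NULL, ...) {
  fwd <- forward_model(object$spec, object$par)
  idx <- if (is.null(curves)) seq_along(object$spec$dataset) else curves
  df <- dplyr::bind_rows(purrr::map(idx, function(i) {
    cv <- object$spec$dataset[[i]]
    tibble::tibble(curve = factor(i), time = cv$decay$time,
                   measured = cv$decay$counts,
                   model = fwd$model_counts[[i]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured), size = 0.2,
                        alpha = 0.4, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$model, colour = .data$curve)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "counts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot simulated FRET efficiency versus probe separation
#'
#' Displays the helical-periodicity fingerprint of the transfer efficiency
#' as a function of donor-acceptor base separation in a regular helix.
#'
#' @param efficiencies Tibble with columns `separation` and `E` (for example
#'   a fixture manifest).
#' @return A ggplot object.
#' @export
plot_efficiency_profile <- function(efficiencies) {
  ggplot2::ggplot(efficiencies, ggplot2::aes(.data$separation, .data$E)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "base separation (pairs)", y = "FRET efficiency E") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
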
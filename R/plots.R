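# ggplot2 views of the result objects.

#' Plot measured against expected separation
#'
#' The classic validation view: measured cup-head separation against the
#' expected (micrometer) value, with the 45-degree identity line and a
#' +/-0.1 mm band.
#'
#' @param object A `wear_study` or `wear_records` object.
#' @param band Half-width of the tolerance band, mm.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wear_study
#' @export
autoplot.wear_study <- function(object, band = 0.1, ...) {
  autoplot(object$wear, band = band, ...)
}

#' @rdname autoplot.wear_study
#' @method autoplot wear_records
#' @export
autoplot.wear_records <- function(object, band = 0.1, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$expected_separation,
                               y = .data$measured_separation)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "solid",
                         colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = c(-band, band),
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "expected separation (mm)",
                  y = "measured separation (mm)") +
    ggplot2::theme_minimal()
}

#' Plot radial residuals of a sphere fit
#'
#' Residual distance to the fitted sphere per surface point, split by the
#' pruning verdict; a sanity view of what the robust fit kept and discarded.
#'
#' @param object A `sphere_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sphere_fit
#' @export
autoplot.sphere_fit <- function(object, ...) {
  pts <- object$points
  P <- as.matrix(pts[, c("x_mm", "y_mm", "z_mm")])
  pts$residual <- sqrt(rowSums(sweep(P, 2, object$center)^2)) - object$radius
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$residual, fill = .data$valid)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.7) +
    ggplot2::labs(x = "radial residual (mm)", y = "points",
                  fill = "kept") +
    ggplot2::theme_minimal()
}
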
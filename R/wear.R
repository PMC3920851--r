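# Wear analysis: cup-head separation, expected separation from micrometer
# settings, regression against the 45-degree line, summary statistics, and
# the repeatability coefficient.

sphere_center <- function(x) {
  if (inherits(x, "sphere_fit") || inherits(x, "sphere_model")) return(x$center)
  as_point3(x, "sphere center")
}

#' Cup-head separation
#'
#' The Euclidean distance between the fitted cup-sphere center and the
#' fitted head-sphere center; its change over time proxies polyethylene
#' liner wear.
#'
#' @param cup,head `sphere_model` / `sphere_fit` objects (or bare centers).
#' @return Distance in mm.
#' @export
cup_head_separation <- function(cup, head) {
  sqrt(sum((sphere_center(cup) - sphere_center(head))^2))
}

#' Expected separation from micrometer settings
#'
#' The Euclidean norm of the displacement triple applied between a scan and
#' the zero-displacement reference.
#'
#' @param dx,dy,dz Micrometer displacements, mm (vectorised).
#' @return Expected separation(s) in mm.
#' @export
expected_separation <- function(dx, dy, dz) {
  stopifnot(all(is.finite(dx)), all(is.finite(dy)), all(is.finite(dz)))
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Build wear records from measured and expected separations
#'
#' @param scan_id Character scan identifiers.
#' @param measured,expected Separations in mm.
#' @return A `wear_records` tibble with `difference = measured - expected`.
#' @export
wear_records <- function(scan_id, measured, expected) {
  structure(tibble(scan_id = as.character(scan_id),
                   measured_separation = measured,
                   expected_separation = expected,
                   difference = measured - expected),
            class = c("wear_records", class(tibble())))
}

#' Regression of measured on expected separation
#'
#' Ordinary least squares of the measured cup-head separation on the
#' expected (micrometer) separation. A perfect measurement chain gives the
#' 45-degree line: slope 1, intercept 0.
#'
#' @param records A `wear_records` tibble (or any data frame with columns
#'   `measured_separation`, `expected_separation`).
#' @return Object of class `wear_regression` with slope, intercept, their
#'   standard errors and p-values, `residual_sd`, `f_value` and the
#'   underlying `lm` fit.
#' @export
wear_regression <- function(records) {
  if (nrow(records) < 3L ||
      length(unique(records$expected_separation)) < 2L) {
    stop_hipwear(
      "need at least 3 records with non-constant expected separations",
      "hipwear_degenerate_design")
  }
  fit <- lm(measured_separation ~ expected_separation, data = records)
  s <- summary(fit)
  co <- s$coefficients
  structure(list(slope = co[2, 1], intercept = co[1, 1],
                 slope_se = co[2, 2], intercept_se = co[1, 2],
                 slope_p = co[2, 4], intercept_p = co[1, 4],
                 residual_sd = s$sigma,
                 f_value = unname(s$fstatistic[1]),
                 n = nrow(records), fit = fit),
            class = "wear_regression")
}

#' @export
print.wear_regression <- function(x, ...) {
  cat(sprintf(paste0("<wear_regression> measured ~ expected (n = %d)\n",
                     "  slope %.3f (SE %.3f, p = %.3g)\n",
                     "  intercept %.3f mm (SE %.3f, p = %.3g)\n",
                     "  residual SD %.3f mm, F = %.1f\n"),
              x$n, x$slope, x$slope_se, x$slope_p,
              x$intercept, x$intercept_se, x$intercept_p,
              x$residual_sd, x$f_value))
  invisible(x)
}

#' @describeIn wear_regression Broom-style term table.
#' @param x A `wear_regression`.
#' @param ... Unused.
#' @method tidy wear_regression
#' @export
tidy.wear_regression <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se),
         p.value = c(x$intercept_p, x$slope_p))
}

#' @describeIn wear_regression Broom-style one-row summary.
#' @method glance wear_regression
#' @export
glance.wear_regression <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         residual_sd = x$residual_sd, f_value = x$f_value, n = x$n)
}

#' Summary statistics with a t confidence interval
#'
#' Mean, median, SD, coefficient of variation (percent) and a two-sided
#' t-based confidence interval of the mean (99% by default).
#'
#' @param values Numeric sample (n >= 2).
#' @param confidence Confidence level.
#' @return One-row tibble: `n`, `mean`, `median`, `sd`,
#'   `coefficient_of_variation`, `ci_lower`, `ci_upper`, `confidence`.
#' @export
summary_stats <- function(values, confidence = 0.99) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) {
    stop_hipwear("need at least 2 values for summary statistics",
                 "hipwear_insufficient_points")
  }
  m <- mean(values); s <- sd(values)
  half <- qt(1 - (1 - confidence) / 2, df = n - 1) * s / sqrt(n)
  tibble(n = n, mean = m, median = median(values), sd = s,
         coefficient_of_variation = if (m != 0) 100 * s / abs(m) else NA_real_,
         ci_lower = m - half, ci_upper = m + half, confidence = confidence)
}

#' Repeatability coefficient of paired measurements
#'
#' Precision under repeated measurement of the same item by the same method
#' and observer within a short interval. With paired trials, the within-pair
#' standard deviation is `s_r = sqrt(sum(d_i^2) / (2 n))` for pair
#' differences `d_i`, and the repeatability coefficient is `2.77 * s_r`
#' (ISO 5725 convention, 2.77 = 1.96 * sqrt(2)): the absolute difference of
#' two future repeats is below it with ~95% probability.
#'
#' @param trial1,trial2 Paired measurement vectors, or `trial1` may be a
#'   two-column matrix / data frame of pairs.
#' @param confidence Confidence level for the interval on the mean pair
#'   difference.
#' @return Object of class `repeatability`: `coefficient`, `within_sd`, `n`,
#'   and a `differences` one-row tibble from [summary_stats()].
#' @export
repeatability <- function(trial1, trial2 = NULL, confidence = 0.99) {
  if (is.null(trial2)) {
    m <- as.matrix(trial1)
    stopifnot(ncol(m) == 2L)
    trial1 <- m[, 1]; trial2 <- m[, 2]
  }
  if (length(trial1) != length(trial2) || length(trial1) < 2L) {
    stop_hipwear("need at least 2 measurement pairs of equal length",
                 "hipwear_insufficient_points")
  }
  d <- trial1 - trial2
  s_r <- sqrt(sum(d^2) / (2 * length(d)))
  structure(list(coefficient = 2.77 * s_r,
                 within_sd = s_r,
                 n = length(d),
                 differences = summary_stats(d, confidence = confidence)),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf(paste0("<repeatability> coefficient %.4f mm ",
                     "(within-pair SD %.4f mm, n = %d pairs)\n",
                     "  pair differences: mean %.4f, median %.4f, SD %.4f mm\n"),
              x$coefficient, x$within_sd, x$n,
              x$differences$mean, x$differences$median, x$differences$sd))
  invisible(x)
}
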
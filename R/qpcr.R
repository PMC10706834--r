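# qPCR comparator: standard curves, Ct interpolation, relative quantity.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 concentration over a dilution
#' series. Amplification efficiency follows from the slope as
#' `100 * (10^(-1/slope) - 1)` percent (a slope of -3.3219 corresponds to
#' perfect per-cycle doubling, 100%).
#'
#' @param concentrations_ng_ul Dilution-series concentrations (> 0), >= 3
#'   points.
#' @param ct_values Matching Ct values.
#' @param species_label Optional label carried in the result.
#' @return Object of class `"standard_curve"`: `slope`, `intercept`,
#'   `r_squared`, `efficiency_pct`, `species_label`, `positive_slope`
#'   (validity flag), and the fitting data. Supports `print()`, `coef()`,
#'   `predict()` (Ct -> ng/uL) and `plot()`.
#' @examples
#' conc <- qpcr_dilution_series()
#' ct <- -3.506 * log10(conc) + 31.88
#' fit_standard_curve(conc, ct, "rainbow trout")
#' @export
fit_standard_curve <- function(concentrations_ng_ul, ct_values,
                               species_label = "") {
  if (length(concentrations_ng_ul) != length(ct_values))
    stop("concentration and Ct vectors must have equal length", call. = FALSE)
  if (length(concentrations_ng_ul) < 3L)
    stop("at least three dilution points are required", call. = FALSE)
  if (any(concentrations_ng_ul <= 0))
    stop("concentrations must be positive", call. = FALSE)
  x <- log10(concentrations_ng_ul)
  fit <- stats::lm(ct_values ~ x)
  slope <- unname(stats::coef(fit)[2])
  positive_slope <- slope >= 0
  if (positive_slope)
    warning("standard curve has non-negative slope; dilution series invalid",
            call. = FALSE)
  r2 <- if (stats::var(ct_values) == 0) 1 else stats::cor(x, ct_values)^2
  structure(list(species_label = species_label, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency_pct = 100 * (10^(-1 / slope) - 1),
                 positive_slope = positive_slope,
                 data = data.frame(log10_conc = x, ct = ct_values)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  lab <- if (nzchar(x$species_label)) paste0(" (", x$species_label, ")") else ""
  cat(sprintf("qPCR standard curve%s\n", lab))
  cat(sprintf("  Ct = %.3f * log10(conc) + %.2f\n", x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f, efficiency = %.2f%%\n",
              x$r_squared, x$efficiency_pct))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @param object A `"standard_curve"`.
#' @param ct Ct values to interpolate.
#' @param ... Unused.
#' @rdname fit_standard_curve
#' @export
predict.standard_curve <- function(object, ct, ...) {
  vapply(ct, interpolate_concentration, numeric(1), curve = object)
}

#' @export
plot.standard_curve <- function(x, ...) {
  graphics::plot(x$data$log10_conc, x$data$ct,
                 xlab = "log10 concentration (ng/uL)", ylab = "Ct",
                 main = sprintf("qPCR standard curve %s", x$species_label),
                 ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' Interpolate a DNA concentration from a Ct value
#'
#' Inverts the fitted line: `conc = 10^((ct - intercept) / slope)`.
#'
#' @param ct Observed Ct.
#' @param curve A `"standard_curve"`.
#' @return Concentration in ng/uL.
#' @export
interpolate_concentration <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("curve slope is zero", call. = FALSE)
  10^((ct - curve$intercept) / curve$slope)
}

#' Relative quantity of trout DNA
#'
#' qPCR relative quantification: `P_O (%) = 100 * c_o / (c_o + c_s)`, the
#' trout share of total interpolated DNA concentration. Unlike the ddPCR
#' one-step formula this applies no copies-per-mass correction; the resulting
#' systematic bias relative to ddPCR is inherent to the comparator.
#'
#' @param c_o,c_s Interpolated trout / salmon DNA concentrations (>= 0, not
#'   both zero).
#' @return P_O in percent.
#' @examples
#' relative_quantity(3, 1) # 75
#' @export
relative_quantity <- function(c_o, c_s) {
  if (c_o < 0 || c_s < 0) stop("concentrations must be >= 0", call. = FALSE)
  if (c_o == 0 && c_s == 0)
    stop("no template detected in either assay", call. = FALSE)
  100 * c_o / (c_o + c_s)
}
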
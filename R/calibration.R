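# Transfer-coefficient (K) calibration.
#
# The duplex assay measures copy concentrations Q_O (trout) and Q_S (salmon).
# Because the myoglobin gene is single-copy, copies per unit mass (C_O, C_S)
# are species constants, and the mass ratio follows from
#   M_O/M_S = (C_S/C_O) * (Q_O/Q_S) = K * (Q_O/Q_S).
# K is calibrated from mixtures of known mass fraction.

#' Per-mixture transfer coefficient
#'
#' For a mixture with known trout mass fraction `f` (percent) and measured
#' concentrations, `K = (f/(100-f)) * (q_s/q_o)`.
#'
#' @param trout_fraction_pct Known trout mass fraction, strictly inside
#'   `(0, 100)`.
#' @param q_o,q_s Measured trout / salmon concentrations (copies/uL), > 0.
#' @return K value (numeric scalar).
#' @examples
#' k_from_mixture(30, 101.23, 97.79) # ~0.414
#' @export
k_from_mixture <- function(trout_fraction_pct, q_o, q_s) {
  if (any(trout_fraction_pct <= 0 | trout_fraction_pct >= 100))
    stop("mass fraction must lie strictly between 0 and 100 percent",
         call. = FALSE)
  if (any(q_o <= 0) || any(q_s <= 0))
    stop("concentrations must be positive", call. = FALSE)
  (trout_fraction_pct / (100 - trout_fraction_pct)) * (q_s / q_o)
}

#' Calibrate the transfer coefficient K
#'
#' Fits the copy-ratio-to-mass-ratio conversion constant from calibration
#' mixtures. One K value is computed per mixture level from the
#' replicate-mean concentrations, then averaged; spread is summarised as the
#' relative standard deviation. With
#' `rounding_mode = "two_decimals"` the per-level K values are rounded to two
#' decimals before averaging, matching how calibration tables are typically
#' reported; the default `"raw"` keeps full precision.
#'
#' @param points Data frame with columns `trout_mass_fraction_pct`, `q_o`,
#'   `q_s` (replicate-mean copies/uL per mixture level); at least two rows.
#' @param rounding_mode `"raw"` or `"two_decimals"`.
#' @return Object of class `"k_calibration"` with components `k_mean`,
#'   `k_rsd_pct`, `points` (input plus `k_value`), `rounding_mode`, `n`.
#'   Supports `print()`, `summary()`, `coef()` and `predict()` (mass
#'   fractions for new `q_o`/`q_s` pairs).
#' @examples
#' pts <- data.frame(trout_mass_fraction_pct = c(10, 30, 50, 70, 90),
#'                   q_o = c(94.00, 101.23, 121.30, 183.50, 226.50),
#'                   q_s = c(376.5, 97.79, 51.57, 34.78, 11.13))
#' fit <- estimate_K(pts)
#' coef(fit)
#' @export
estimate_K <- function(points, rounding_mode = c("raw", "two_decimals")) {
  rounding_mode <- match.arg(rounding_mode)
  stopifnot(is.data.frame(points),
            all(c("trout_mass_fraction_pct", "q_o", "q_s") %in% names(points)))
  if (nrow(points) < 2L)
    stop("at least two calibration points are required", call. = FALSE)
  k <- k_from_mixture(points$trout_mass_fraction_pct, points$q_o, points$q_s)
  if (rounding_mode == "two_decimals") k <- round(k, 2)
  points$k_value <- k
  structure(list(k_mean = mean(k),
                 k_rsd_pct = 100 * stats::sd(k) / mean(k),
                 points = points, rounding_mode = rounding_mode,
                 n = nrow(points)),
            class = "k_calibration")
}

#' @export
print.k_calibration <- function(x, digits = 3, ...) {
  cat(sprintf("Transfer-coefficient calibration (%d mixture levels, %s)\n",
              x$n, x$rounding_mode))
  cat(sprintf("  K = %s  (RSD %.2f%%)\n",
              format(x$k_mean, digits = digits), x$k_rsd_pct))
  invisible(x)
}

#' @export
summary.k_calibration <- function(object, ...) {
  cat(sprintf("Transfer-coefficient calibration, rounding mode '%s'\n\n",
              object$rounding_mode))
  print(object$points, row.names = FALSE)
  cat(sprintf("\nK mean: %.4f\nRSD:    %.2f %%\n",
              object$k_mean, object$k_rsd_pct))
  invisible(object)
}

#' @export
coef.k_calibration <- function(object, ...) c(K = object$k_mean)

#' Predict mass fractions from measured copy concentrations
#'
#' @param object A `"k_calibration"` fit.
#' @param newdata Data frame with columns `q_o` and `q_s`.
#' @param ... Unused.
#' @return Numeric vector of trout mass fractions (percent).
#' @export
predict.k_calibration <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), all(c("q_o", "q_s") %in% names(newdata)))
  mapply(mass_fraction_percent, newdata$q_o, newdata$q_s,
         MoreArgs = list(k = object$k_mean))
}

#' Verify a calibrated K against mixtures of known composition
#'
#' Applies the one-step formula with the calibrated `k` to measured copy
#' ratios of mixtures with known fractions and reports signed relative
#' deviations.
#'
#' @param known_fractions_pct Known trout mass fractions (percent).
#' @param measured_ratios Measured `q_o / q_s` copy ratios, same length.
#' @param k Transfer coefficient (> 0).
#' @return Data frame: `actual_pct`, `measured_pct`, `deviation_pct`.
#' @examples
#' verify_K(c(20, 40, 60, 80), c(1.2, 3.1, 6.6, 18.1), k = 0.43)
#' @export
verify_K <- function(known_fractions_pct, measured_ratios, k) {
  if (length(known_fractions_pct) != length(measured_ratios))
    stop("fraction and ratio vectors must have equal length", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  measured <- vapply(measured_ratios, function(r) {
    100 * k * r / (1 + k * r)
  }, numeric(1))
  data.frame(actual_pct = known_fractions_pct,
             measured_pct = measured,
             deviation_pct = mapply(relative_deviation, measured,
                                    known_fractions_pct))
}

#' The published transfer coefficient
#'
#' Packaged default K = 0.43 for rainbow trout in Atlantic salmon with the
#' myoglobin duplex assay; a fresh [estimate_K()] calibration overrides it.
#'
#' @return Numeric scalar, 0.43.
#' @export
default_k <- function() 0.43
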
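# Method validation: deviation/RSD metrics, dynamic-range regression,
# LOD/LOQ decision rules, precision summaries, one-way ANOVA.

#' Signed relative deviation (percent)
#'
#' `100 * (measured - actual) / actual`.
#'
#' @param measured,actual Numeric scalars; `actual != 0`.
#' @return Percent deviation, signed.
#' @examples
#' relative_deviation(58.65, 60) # -2.25
#' @export
relative_deviation <- function(measured, actual) {
  if (actual == 0)
    stop("relative deviation undefined for actual value 0", call. = FALSE)
  100 * (measured - actual) / actual
}

#' Relative standard deviation (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(0.44, 0.41, 0.43, 0.44, 0.44)) # ~3.02
#' @export
rsd <- function(values) {
  if (length(values) < 2L)
    stop("at least two values are required", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Dynamic-range linear regression
#'
#' Ordinary least squares of measured on actual mass fractions, used to
#' establish the linear range of the quantification method.
#'
#' @param actual_pcts,measured_pcts Equal-length numeric vectors (>= 3
#'   points; 2 points give an exact interpolation).
#' @return List `slope`, `intercept`, `r_squared`, and the underlying `lm`
#'   fit.
#' @export
dynamic_range_fit <- function(actual_pcts, measured_pcts) {
  if (length(actual_pcts) != length(measured_pcts))
    stop("input vectors must have equal length", call. = FALSE)
  if (length(actual_pcts) < 2L)
    stop("at least two points are required", call. = FALSE)
  if (stats::var(actual_pcts) == 0)
    stop("degenerate fit: no variance in actual values", call. = FALSE)
  fit <- stats::lm(measured_pcts ~ actual_pcts)
  r2 <- if (stats::var(measured_pcts) == 0) 1 else
    stats::cor(actual_pcts, measured_pcts)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, fit = fit)
}

#' Limit of detection from detection rates
#'
#' The LOD is the lowest tested mass fraction detected in 100% of replicates
#' such that every larger tested fraction is also detected in 100% of
#' replicates ("stable detection").
#'
#' @param levels Data frame with columns `fraction_pct` (ascending) and
#'   `detection_rate_pct`.
#' @return LOD (percent mass fraction) or `NA` if no level qualifies.
#' @examples
#' determine_lod(data.frame(
#'   fraction_pct = c(0.05, 0.1, 0.2, 0.5, 0.8, 1, 5),
#'   detection_rate_pct = c(0, 75, 100, 100, 100, 100, 100))) # 0.2
#' @export
determine_lod <- function(levels) {
  stopifnot(is.data.frame(levels),
            all(c("fraction_pct", "detection_rate_pct") %in% names(levels)))
  if (is.unsorted(levels$fraction_pct, strictly = TRUE))
    stop("levels must be sorted ascending by fraction", call. = FALSE)
  ok <- levels$detection_rate_pct == 100
  # all levels from the answer upwards must pass
  pass_up <- rev(cumprod(rev(ok))) == 1
  if (!any(pass_up)) return(NA_real_)
  levels$fraction_pct[which(pass_up)[1]]
}

#' Limit of quantification from relative deviations
#'
#' The LOQ is the lowest tested mass fraction whose absolute relative
#' deviation is within `max_abs_deviation` such that every larger tested
#' fraction also passes (a single failing level below the answer does not
#' block it; a failure above it would).
#'
#' @param levels Data frame with columns `fraction_pct` (ascending) and
#'   `deviation_pct` (signed).
#' @param max_abs_deviation Acceptable absolute deviation, percent
#'   (default 25, the CAC/GL 74-2010 criterion).
#' @return LOQ (percent mass fraction) or `NA`.
#' @examples
#' determine_loq(data.frame(
#'   fraction_pct = c(0.2, 0.5, 0.8, 1, 5),
#'   deviation_pct = c(81.89, -25.52, -4.52, 15.28, 10.10))) # 0.8
#' @export
determine_loq <- function(levels, max_abs_deviation = 25) {
  stopifnot(is.data.frame(levels),
            all(c("fraction_pct", "deviation_pct") %in% names(levels)))
  if (is.unsorted(levels$fraction_pct, strictly = TRUE))
    stop("levels must be sorted ascending by fraction", call. = FALSE)
  ok <- abs(levels$deviation_pct) <= max_abs_deviation
  pass_up <- rev(cumprod(rev(ok))) == 1
  if (!any(pass_up)) return(NA_real_)
  levels$fraction_pct[which(pass_up)[1]]
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) across
#' groups, as used to test whether temperature treatments or food additives
#' shift the quantification result.
#'
#' @param groups List of numeric vectors, >= 2 groups with >= 2 observations
#'   each.
#' @return List `F`, `df1`, `df2`, `p`, `degenerate` (`TRUE` when the
#'   within-group variance is zero while group means differ, in which case
#'   `F = Inf` and `p = 0`).
#' @examples
#' one_way_anova(list(c(0, 1), c(2, 3)))
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L)
    stop("at least two groups are required", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least two observations", call. = FALSE)
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  ssw <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  ssb <- sum(tapply(values, g, length) *
               (tapply(values, g, mean) - mean(values))^2)
  if (ssw == 0 && ssb > 0)
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = unname(ow$p.value),
       degenerate = FALSE)
}

#' Repeatability and reproducibility summary
#'
#' Repeatability is the RSD across replicates within one run (operator x day
#' cell); reproducibility is the RSD across the run cells' means. Both are
#' reported per mixture level, plus their averages across levels.
#'
#' @param data Data frame with columns `level` (mixture fraction or label),
#'   `run` (run/operator/day cell identifier) and `value` (measured
#'   fraction).
#' @return List with `per_level` (data frame: `level`,
#'   `repeatability_rsd_pct`, `reproducibility_rsd_pct`),
#'   `avg_repeatability_rsd_pct`, `avg_reproducibility_rsd_pct`.
#' @export
precision_summary <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("level", "run", "value") %in% names(data)))
  lv <- unique(data$level)
  per <- lapply(lv, function(l) {
    d <- data[data$level == l, ]
    within_rsd <- vapply(split(d$value, d$run), rsd, numeric(1))
    cell_means <- vapply(split(d$value, d$run), mean, numeric(1))
    data.frame(level = l,
               repeatability_rsd_pct = mean(within_rsd),
               reproducibility_rsd_pct = if (length(cell_means) > 1L)
                 rsd(cell_means) else NA_real_)
  })
  per <- do.call(rbind, per)
  list(per_level = per,
       avg_repeatability_rsd_pct = mean(per$repeatability_rsd_pct),
       avg_reproducibility_rsd_pct = mean(per$reproducibility_rsd_pct,
                                          na.rm = TRUE))
}
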
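# Poisson inversion of droplet counts into absolute concentrations.

#' A single well/channel droplet reading
#'
#' @param well_id,sample_id Identifiers.
#' @param channel Fluorescence channel, `"FAM"` (trout) or `"HEX"` (salmon).
#' @param n_total Total accepted droplets (> 0).
#' @param n_positive Positive droplets, `0 <= n_positive <= n_total`.
#' @param droplet_volume_nl Droplet volume in nanolitres (QX200 convention
#'   0.85 nL).
#' @return Object of class `"well_reading"`.
#' @export
well_reading <- function(well_id, sample_id, channel = c("FAM", "HEX"),
                         n_total, n_positive, droplet_volume_nl = 0.85) {
  channel <- match.arg(channel)
  n_total <- as.integer(n_total)
  n_positive <- as.integer(n_positive)
  if (is.na(n_total) || n_total <= 0L)
    stop("n_total must be a positive integer", call. = FALSE)
  if (is.na(n_positive) || n_positive < 0L || n_positive > n_total)
    stop("n_positive must satisfy 0 <= n_positive <= n_total", call. = FALSE)
  if (!is.numeric(droplet_volume_nl) || droplet_volume_nl <= 0)
    stop("droplet_volume_nl must be positive", call. = FALSE)
  structure(list(well_id = well_id, sample_id = sample_id, channel = channel,
                 n_total = n_total, n_positive = n_positive,
                 droplet_volume_nl = droplet_volume_nl),
            class = "well_reading")
}

#' Mean copies per droplet from droplet counts
#'
#' Inverts the Poisson zero-class: with droplets holding Poisson(lambda)
#' template copies, the negative fraction is `exp(-lambda)`, so
#' `lambda = -log((n_total - n_positive) / n_total)`.
#'
#' @param n_total Total droplets (> 0).
#' @param n_positive Positive droplets.
#' @return `lambda_hat`, mean copies per droplet.
#' @examples
#' estimate_lambda(20000, 12642) # ~1.0
#' @export
estimate_lambda <- function(n_total, n_positive) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_positive < 0 || n_positive > n_total)
    stop("n_positive must satisfy 0 <= n_positive <= n_total", call. = FALSE)
  if (n_positive == n_total)
    stop("saturated well: all droplets positive, lambda is unbounded",
         call. = FALSE)
  -log((n_total - n_positive) / n_total)
}

# Wilson score interval for a binomial proportion, without continuity
# correction; stable at extreme counts.
.wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Absolute concentration from a well reading
#'
#' Converts droplet counts to copies per microlitre of reaction:
#' `copies_per_ul = lambda_hat / v` with `v` the droplet volume in uL.
#' The confidence interval is a Wilson score interval on the positive
#' fraction `p`, mapped through the monotone transform
#' `lambda = -log(1 - p)`.
#'
#' @param reading A [well_reading()].
#' @param conf_level Confidence level for the interval.
#' @param allow_saturated If `TRUE`, a fully positive well returns a
#'   `saturated = TRUE` estimate (with `Inf` point estimate) instead of an
#'   error.
#' @return Object of class `"copy_estimate"`: `lambda_hat`, `copies_per_ul`,
#'   `ci_low`, `ci_high`, `saturated`, plus channel/sample metadata.
#' @examples
#' w <- well_reading("A01", "s1", "FAM", 20000, 3000)
#' estimate_concentration(w)
#' @export
estimate_concentration <- function(reading, conf_level = 0.95,
                                   allow_saturated = FALSE) {
  stopifnot(inherits(reading, "well_reading"))
  v_ul <- reading$droplet_volume_nl * 1e-3
  if (reading$n_positive == reading$n_total) {
    if (!allow_saturated)
      stop("saturated well: all droplets positive, lambda is unbounded",
           call. = FALSE)
    est <- list(lambda_hat = Inf, copies_per_ul = Inf,
                ci_low = -log(1 - .wilson_ci(reading$n_positive,
                                             reading$n_total,
                                             conf_level)["low"]) / v_ul,
                ci_high = Inf, saturated = TRUE)
  } else {
    lam <- estimate_lambda(reading$n_total, reading$n_positive)
    ci_p <- .wilson_ci(reading$n_positive, reading$n_total, conf_level)
    est <- list(lambda_hat = lam, copies_per_ul = lam / v_ul,
                ci_low = -log(1 - ci_p[["low"]]) / v_ul,
                ci_high = -log(1 - ci_p[["high"]]) / v_ul,
                saturated = FALSE)
  }
  structure(c(est, list(conf_level = conf_level,
                        well_id = reading$well_id,
                        sample_id = reading$sample_id,
                        channel = reading$channel,
                        n_total = reading$n_total,
                        n_positive = reading$n_positive)),
            class = "copy_estimate")
}

#' @export
print.copy_estimate <- function(x, ...) {
  if (x$saturated) {
    cat(sprintf("[%s %s] saturated well (%d/%d positive), >= %.1f copies/uL\n",
                x$well_id, x$channel, x$n_positive, x$n_total, x$ci_low))
  } else {
    cat(sprintf(
      "[%s %s] lambda = %.4f, %.2f copies/uL (%.0f%% CI %.2f-%.2f)\n",
      x$well_id, x$channel, x$lambda_hat, x$copies_per_ul,
      100 * x$conf_level, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Pool replicate concentration estimates
#'
#' @param estimates List of `"copy_estimate"` objects for the same sample and
#'   channel. Saturated estimates are rejected.
#' @return List with `mean`, `sd` (sample SD, n-1 denominator), `n`,
#'   `channel`, `sample_id`.
#' @examples
#' ws <- lapply(c(2990, 3010, 3000), function(p)
#'   well_reading("w", "s1", "FAM", 20000, p))
#' pool_replicates(lapply(ws, estimate_concentration))
#' @export
pool_replicates <- function(estimates) {
  if (!length(estimates)) stop("no estimates to pool", call. = FALSE)
  stopifnot(all(vapply(estimates, inherits, logical(1), "copy_estimate")))
  ch <- unique(vapply(estimates, `[[`, character(1), "channel"))
  if (length(ch) != 1L)
    stop("cannot pool estimates from mixed channels: ",
         paste(ch, collapse = ", "), call. = FALSE)
  if (any(vapply(estimates, `[[`, logical(1), "saturated")))
    stop("cannot pool saturated estimates", call. = FALSE)
  x <- vapply(estimates, `[[`, numeric(1), "copies_per_ul")
  list(mean = mean(x), sd = stats::sd(x), n = length(x), channel = ch,
       sample_id = unique(vapply(estimates, `[[`, character(1), "sample_id")))
}
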
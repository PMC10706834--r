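# One-step mass-fraction quantification of unknown samples.

#' Meat mass ratio from copy concentrations
#'
#' `M_O/M_S = K * Q_O/Q_S`. A sample with salmon copies but no trout copies
#' has ratio 0; trout copies with no salmon copies give `Inf` (pure trout).
#'
#' @param q_o,q_s Trout / salmon concentrations, copies/uL (>= 0, not both 0).
#' @param k Transfer coefficient (> 0).
#' @return Mass ratio `M_O/M_S` (possibly `Inf`).
#' @examples
#' mass_ratio(183.50, 34.78, 0.43) # ~2.27
#' @export
mass_ratio <- function(q_o, q_s, k = default_k()) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (q_o < 0 || q_s < 0) stop("concentrations must be >= 0", call. = FALSE)
  if (q_o == 0 && q_s == 0)
    stop("no template detected in either channel", call. = FALSE)
  if (q_s == 0) return(Inf)
  k * q_o / q_s
}

#' Trout mass fraction (percent) from copy concentrations
#'
#' Converts the mass ratio `r = K q_o/q_s` into a percentage of total mass,
#' `100 r / (1 + r)`; 0 when no trout copies, 100 when no salmon copies.
#'
#' @inheritParams mass_ratio
#' @return Mass fraction in `[0, 100]` percent.
#' @export
mass_fraction_percent <- function(q_o, q_s, k = default_k()) {
  r <- mass_ratio(q_o, q_s, k)
  if (is.infinite(r)) return(100)
  100 * r / (1 + r)
}

#' Quantify one sample from replicate duplex wells
#'
#' Estimates per-replicate concentrations by Poisson inversion, converts each
#' replicate's copy ratio into a trout mass fraction, and summarises
#' replicates as mean, SD and RSD. The qualitative call thresholds the mean
#' fraction at the limits of the scale with a tolerance equal to the limit of
#' detection: mean <= `lod_pct` is `not_detected`, mean >=
#' `100 - lod_pct` is `pure_trout`, anything else `adulterated`.
#'
#' @param wells Data frame of replicate duplex readings for one sample, in
#'   the plate dialect (`well_id`, `channel`, `n_total`, `n_positive`,
#'   optional `droplet_volume_nl`); each `well_id` must appear once per
#'   channel. Saturated wells are dropped with a warning.
#' @param k Transfer coefficient.
#' @param lod_pct Limit of detection used as call tolerance (percent).
#' @param conf_level Confidence level passed to [estimate_concentration()].
#' @return Object of class `"quant_result"`: `sample_id`, per-replicate
#'   table, `mass_ratio` (from mean concentrations), `trout_fraction_pct`
#'   (replicate mean), `replicate_sd`, `rsd_pct`, `call`.
#' @export
quantify_sample <- function(wells, k = default_k(), lod_pct = 0.2,
                            conf_level = 0.95) {
  stopifnot(is.data.frame(wells),
            all(c("well_id", "channel", "n_total", "n_positive")
                %in% names(wells)))
  if (is.null(wells$droplet_volume_nl)) wells$droplet_volume_nl <- 0.85
  if (is.null(wells$sample_id)) wells$sample_id <- "sample"
  sample_id <- unique(wells$sample_id)
  if (length(sample_id) != 1L)
    stop("quantify_sample expects wells from a single sample", call. = FALSE)

  ids <- unique(wells$well_id)
  reps <- list()
  for (w in ids) {
    fam <- wells[wells$well_id == w & wells$channel == "FAM", ]
    hex <- wells[wells$well_id == w & wells$channel == "HEX", ]
    if (nrow(fam) != 1L || nrow(hex) != 1L)
      stop(sprintf("well '%s' is not a duplex pair (one FAM + one HEX row)",
                   w), call. = FALSE)
    if (fam$n_positive == fam$n_total || hex$n_positive == hex$n_total) {
      warning(sprintf("dropping saturated well '%s'", w), call. = FALSE)
      next
    }
    q_o <- estimate_concentration(
      well_reading(w, sample_id, "FAM", fam$n_total, fam$n_positive,
                   fam$droplet_volume_nl), conf_level)$copies_per_ul
    q_s <- estimate_concentration(
      well_reading(w, sample_id, "HEX", hex$n_total, hex$n_positive,
                   hex$droplet_volume_nl), conf_level)$copies_per_ul
    frac <- if (q_o == 0 && q_s == 0) NA_real_ else
      mass_fraction_percent(q_o, q_s, k)
    reps[[length(reps) + 1L]] <- data.frame(
      well_id = w, q_o = q_o, q_s = q_s, trout_fraction_pct = frac,
      stringsAsFactors = FALSE)
  }
  if (!length(reps))
    stop("quantification failure: no usable (non-saturated) wells",
         call. = FALSE)
  reps <- do.call(rbind, reps)
  if (all(is.na(reps$trout_fraction_pct)))
    stop("quantification failure: no template detected in any replicate",
         call. = FALSE)

  fr <- reps$trout_fraction_pct[!is.na(reps$trout_fraction_pct)]
  mean_f <- mean(fr)
  sd_f <- if (length(fr) > 1L) stats::sd(fr) else NA_real_
  q_o_mean <- mean(reps$q_o)
  q_s_mean <- mean(reps$q_s)
  mr <- if (q_o_mean == 0 && q_s_mean == 0) NA_real_ else
    mass_ratio(q_o_mean, q_s_mean, k)
  call <- if (mean_f <= lod_pct) "not_detected"
          else if (mean_f >= 100 - lod_pct) "pure_trout"
          else "adulterated"
  structure(list(sample_id = sample_id, replicates = reps,
                 mass_ratio = mr, trout_fraction_pct = mean_f,
                 replicate_sd = sd_f,
                 rsd_pct = if (!is.na(sd_f) && mean_f > 0)
                   100 * sd_f / mean_f else NA_real_,
                 call = call, k = k, lod_pct = lod_pct),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Sample '%s': trout mass fraction %.2f%%", x$sample_id,
              x$trout_fraction_pct))
  if (!is.na(x$replicate_sd))
    cat(sprintf(" +/- %.2f (n = %d, RSD %.2f%%)",
                x$replicate_sd, nrow(x$replicates), x$rsd_pct))
  cat(sprintf("  [%s]\n", x$call))
  invisible(x)
}

#' Quantify every sample on a plate
#'
#' @param plate Plate data frame (see [read_plate()]).
#' @inheritParams quantify_sample
#' @return List of `"quant_result"`, one per sample, named by `sample_id`.
#' @export
quantify_plate <- function(plate, k = default_k(), lod_pct = 0.2) {
  out <- lapply(split(plate, plate$sample_id), quantify_sample,
                k = k, lod_pct = lod_pct)
  out[unique(plate$sample_id)]
}
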
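# Seeded synthetic duplex-ddPCR and qPCR data generation.
#
# The generator reproduces the statistical structure the analysis assumes:
# linear mass->copy mapping per species, one shared lognormal extraction draw
# per replicate (both channels come from the same tube), species-symmetric
# degradation, Poisson template partitioning into ~20,000 droplets, and
# optional per-droplet misclassification.

#' Species copies-per-mass constants
#'
#' Copies of the single-copy myoglobin gene recovered per milligram of meat,
#' for rainbow trout (`c_o`) and Atlantic salmon (`c_s`). Their ratio
#' `c_s / c_o` is the true transfer coefficient K.
#'
#' @param c_o,c_s Copies per mg for trout and salmon. Defaults give
#'   `true_k = 0.43`, the published coefficient, and duplex concentrations of
#'   the order observed in calibration wells (tens to hundreds of copies/uL).
#' @return List with `c_o`, `c_s`, `true_k`.
#' @export
species_constants <- function(c_o = 100, c_s = 43) {
  stopifnot(c_o > 0, c_s > 0)
  list(c_o = c_o, c_s = c_s, true_k = c_s / c_o)
}

#' Simulation configuration
#'
#' @param n_droplets Droplets generated per well.
#' @param droplet_volume_nl Droplet volume, nL.
#' @param fp_rate,fn_rate Per-droplet false-positive / false-negative call
#'   probabilities ("rain"), in `[0, 1)`.
#' @param extraction_cv Lognormal coefficient of variation of the per-replicate
#'   extraction yield; one draw is shared by both channels of a duplex well.
#' @param degradation_factor Fraction of amplifiable copies retained after
#'   thermal/freezing treatment, in `(0, 1]`; applied equally to both species.
#' @param dilution_factor Copies entering one uL of reaction per extracted
#'   copy of template (collapses extraction yield, elution volume and
#'   reaction loading into one constant).
#' @param seed Integer seed; every stochastic generator in the package is
#'   driven from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_droplets = 20000L, droplet_volume_nl = 0.85,
                       fp_rate = 0, fn_rate = 0, extraction_cv = 0.05,
                       degradation_factor = 1.0, dilution_factor = 0.025,
                       seed = 1L) {
  stopifnot(n_droplets > 0, droplet_volume_nl > 0,
            fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate < 1,
            extraction_cv >= 0, degradation_factor > 0,
            degradation_factor <= 1, dilution_factor > 0)
  structure(list(n_droplets = as.integer(n_droplets),
                 droplet_volume_nl = droplet_volume_nl,
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 extraction_cv = extraction_cv,
                 degradation_factor = degradation_factor,
                 dilution_factor = dilution_factor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' A binary mixture sample
#'
#' @param sample_id Identifier.
#' @param trout_mass_fraction_pct Declared rainbow trout mass fraction, in
#'   `[0, 100]` percent.
#' @param total_mass_mg Total meat mass extracted (default 100 mg).
#' @return List of class `"mixture_sample"`.
#' @export
mixture_sample <- function(sample_id, trout_mass_fraction_pct,
                           total_mass_mg = 100) {
  stopifnot(trout_mass_fraction_pct >= 0, trout_mass_fraction_pct <= 100,
            total_mass_mg > 0)
  structure(list(sample_id = sample_id,
                 trout_mass_fraction_pct = trout_mass_fraction_pct,
                 total_mass_mg = total_mass_mg),
            class = "mixture_sample")
}

# deterministic substream seed below 2^31 derived from (seed, counter)
.substream_seed <- function(seed, counter) {
  as.integer((abs(as.numeric(seed)) %% 65536 * 104729 +
                as.numeric(counter) * 7919 + 13) %% 2147483629)
}

#' Simulate true template concentrations for one replicate of a mixture
#'
#' Trout copies are proportional to the trout mass and `c_o`, salmon copies
#' to the remaining mass and `c_s`; both are jointly scaled by one lognormal
#' extraction draw (mean 1, CV `extraction_cv`) and by `degradation_factor`.
#' The copy *ratio* is therefore exactly `(f/(100-f)) * (c_o/c_s)` in every
#' replicate - the shared-tube cancellation that makes the ratio method more
#' precise than either single-channel concentration.
#'
#' @param mix A [mixture_sample()].
#' @param consts [species_constants()].
#' @param cfg [sim_config()]; `cfg$seed` drives the extraction draw.
#' @return List `conc_trout`, `conc_salmon` in copies/uL of reaction.
#' @export
simulate_mixture_copies <- function(mix, consts, cfg) {
  stopifnot(inherits(mix, "mixture_sample"), inherits(cfg, "sim_config"))
  f <- mix$trout_mass_fraction_pct
  trout_mg <- mix$total_mass_mg * f / 100
  salmon_mg <- mix$total_mass_mg * (100 - f) / 100
  yield <- 1
  if (cfg$extraction_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$extraction_cv^2))
    old <- .Random.seed_save()
    set.seed(cfg$seed)
    yield <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    .Random.seed_restore(old)
  }
  scale <- cfg$dilution_factor * cfg$degradation_factor * yield
  list(conc_trout = trout_mg * consts$c_o * scale,
       conc_salmon = salmon_mg * consts$c_s * scale)
}

# save/restore helpers so seeded generators do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Simulate one well's droplet counts
#'
#' Each of `n_droplets` droplets holds Poisson(lambda) template copies with
#' `lambda = conc * droplet volume (uL)`. A droplet is called positive iff it
#' holds at least one template and is not flipped by the false-negative rate,
#' or holds none and is flipped by the false-positive rate. The count of
#' positives is drawn in one step as
#' `Binomial(n_droplets, (1 - exp(-lambda)) (1 - fn) + exp(-lambda) fp)`,
#' which is distributionally identical to simulating droplets one by one.
#'
#' @param conc_copies_per_ul True concentration, copies/uL (>= 0).
#' @param cfg [sim_config()].
#' @param channel `"FAM"` or `"HEX"`.
#' @param well_id,sample_id Metadata for the returned reading.
#' @param seed Optional override of `cfg$seed`.
#' @return A [well_reading()].
#' @export
simulate_well <- function(conc_copies_per_ul, cfg, channel = "FAM",
                          well_id = "W01", sample_id = "sim",
                          seed = cfg$seed) {
  stopifnot(conc_copies_per_ul >= 0, inherits(cfg, "sim_config"))
  lambda <- conc_copies_per_ul * cfg$droplet_volume_nl * 1e-3
  p_pos <- (1 - exp(-lambda)) * (1 - cfg$fn_rate) + exp(-lambda) * cfg$fp_rate
  old <- .Random.seed_save()
  set.seed(seed)
  npos <- stats::rbinom(1, cfg$n_droplets, p_pos)
  .Random.seed_restore(old)
  well_reading(well_id, sample_id, channel, cfg$n_droplets, npos,
               cfg$droplet_volume_nl)
}

#' Simulate a qPCR Ct value
#'
#' Ct follows the usual linear model in log10 concentration,
#' `Ct = slope * log10(conc) + intercept + N(0, noise_sd)`.
#'
#' @param conc_ng_per_ul DNA concentration, ng/uL (> 0).
#' @param slope,intercept Standard-curve parameters (slope in Ct per log10
#'   ng/uL, negative for a valid series).
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param seed Integer seed.
#' @return Ct value (numeric scalar).
#' @examples
#' simulate_qpcr_ct(50, -3.506, 31.88, noise_sd = 0) # ~25.92
#' @export
simulate_qpcr_ct <- function(conc_ng_per_ul, slope, intercept, noise_sd = 0,
                             seed = 1L) {
  if (conc_ng_per_ul <= 0)
    stop("concentration must be positive", call. = FALSE)
  ct <- slope * log10(conc_ng_per_ul) + intercept
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    ct <- ct + stats::rnorm(1, 0, noise_sd)
    .Random.seed_restore(old)
  }
  ct
}

#' Generate a full synthetic duplex-ddPCR study
#'
#' For every replicate of every design row a shared extraction draw scales
#' both species' concentrations, then one FAM (trout) and one HEX (salmon)
#' reading are simulated for the same duplex well. Per-well RNG substreams
#' are derived from `cfg$seed` and a running counter, so a well's counts do
#' not depend on the position of its sample in the design.
#'
#' @param design Data frame with columns `sample_id`,
#'   `trout_mass_fraction_pct`, `n_replicates` and optionally
#'   `total_mass_mg`.
#' @param consts [species_constants()].
#' @param cfg [sim_config()].
#' @return Object of class `"ddpcr_study"`: list with `plate` (data frame in
#'   the plate-CSV dialect: `well_id`, `sample_id`, `channel`, `n_total`,
#'   `n_positive`, `droplet_volume_nl`), `truth` (per-replicate true
#'   concentrations and fractions), `consts`, `cfg`.
#' @examples
#' des <- calibration_design()
#' st <- generate_study(des, species_constants(), sim_config(seed = 7))
#' head(st$plate)
#' @export
generate_study <- function(design, consts = species_constants(),
                           cfg = sim_config()) {
  stopifnot(is.data.frame(design),
            all(c("sample_id", "trout_mass_fraction_pct", "n_replicates")
                %in% names(design)))
  if (is.null(design$total_mass_mg)) design$total_mass_mg <- 100
  plate <- list()
  truth <- list()
  counter <- 0L
  widx <- 0L
  for (i in seq_len(nrow(design))) {
    for (r in seq_len(design$n_replicates[i])) {
      widx <- widx + 1L
      well_id <- sprintf("W%03d", widx)
      mix <- mixture_sample(design$sample_id[i],
                            design$trout_mass_fraction_pct[i],
                            design$total_mass_mg[i])
      cfg_rep <- cfg
      cfg_rep$seed <- .substream_seed(cfg$seed, counter); counter <- counter + 1L
      conc <- simulate_mixture_copies(mix, consts, cfg_rep)
      w_fam <- simulate_well(conc$conc_trout, cfg, "FAM", well_id,
                             mix$sample_id,
                             seed = .substream_seed(cfg$seed, counter))
      counter <- counter + 1L
      w_hex <- simulate_well(conc$conc_salmon, cfg, "HEX", well_id,
                             mix$sample_id,
                             seed = .substream_seed(cfg$seed, counter))
      counter <- counter + 1L
      for (w in list(w_fam, w_hex)) {
        plate[[length(plate) + 1L]] <- data.frame(
          well_id = w$well_id, sample_id = w$sample_id, channel = w$channel,
          n_total = w$n_total, n_positive = w$n_positive,
          droplet_volume_nl = w$droplet_volume_nl, stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        well_id = well_id, sample_id = mix$sample_id, replicate = r,
        trout_mass_fraction_pct = mix$trout_mass_fraction_pct,
        conc_trout = conc$conc_trout, conc_salmon = conc$conc_salmon,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(plate = do.call(rbind, plate),
                 truth = do.call(rbind, truth),
                 design = design, consts = consts, cfg = cfg),
            class = "ddpcr_study")
}

#' @export
print.ddpcr_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic duplex ddPCR study: %d samples, %d duplex wells (seed %d)\n",
    nrow(x$design), nrow(x$truth), x$cfg$seed))
  invisible(x)
}

#' Standard study designs
#'
#' `calibration_design()` mirrors the K-estimation layout (mass fractions
#' 10/30/50/70/90 %, six replicates each); `verification_design()` mirrors
#' the K-verification layout (20/40/60/80 %, four replicates each).
#'
#' @param n_replicates Replicates per mixture level.
#' @return Data frame usable as `design` in [generate_study()].
#' @export
calibration_design <- function(n_replicates = 6L) {
  f <- c(10, 30, 50, 70, 90)
  data.frame(sample_id = sprintf("cal_%d", f), trout_mass_fraction_pct = f,
             n_replicates = n_replicates, stringsAsFactors = FALSE)
}

#' @rdname calibration_design
#' @export
verification_design <- function(n_replicates = 4L) {
  f <- c(20, 40, 60, 80)
  data.frame(sample_id = sprintf("ver_%d", f), trout_mass_fraction_pct = f,
             n_replicates = n_replicates, stringsAsFactors = FALSE)
}

#' Four-fold qPCR dilution series
#'
#' @param start_ng_ul Highest concentration (default 50 ng/uL).
#' @param fold Dilution factor between points.
#' @param n Number of points (default 6, reaching 0.05 ng/uL).
#' @return Numeric vector of concentrations.
#' @export
qpcr_dilution_series <- function(start_ng_ul = 50, fold = 4, n = 6) {
  start_ng_ul / fold^(seq_len(n) - 1)
}
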
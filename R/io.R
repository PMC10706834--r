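# Plate CSV dialect, run configuration, and report writers.

PLATE_COLUMNS <- c("well_id", "sample_id", "channel", "n_total", "n_positive")

#' Read a droplet-count plate table
#'
#' The plate dialect is a headered CSV with columns
#' `well_id,sample_id,channel,n_total,n_positive` and an optional
#' `droplet_volume_nl` column; `channel` is `FAM` or `HEX`. Malformed rows
#' are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @param min_droplets Wells with fewer total droplets are flagged in the
#'   `low_droplets` column (conventionally discarded before analysis).
#' @return Validated data frame.
#' @export
read_plate <- function(path, min_droplets = 10000L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PLATE_COLUMNS, names(tab))
  if (length(missing))
    stop("plate format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  line_no <- seq_len(nrow(tab)) + 1L  # header is line 1
  bad <- which(!(tab$channel %in% c("FAM", "HEX")))
  if (length(bad))
    stop("plate format error: invalid channel at line(s) ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  for (col in c("n_total", "n_positive")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop(sprintf("plate format error: non-integer or negative %s at line(s) %s",
                   col, paste(line_no[bad], collapse = ", ")), call. = FALSE)
    tab[[col]] <- v
  }
  bad <- which(tab$n_total == 0L)
  if (length(bad))
    stop("plate validation error: n_total must be > 0 at line(s) ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  bad <- which(tab$n_positive > tab$n_total)
  if (length(bad))
    stop("plate validation error: n_positive > n_total at line(s) ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  dup <- duplicated(tab[, c("well_id", "channel")])
  if (any(dup))
    stop("plate format error: duplicate (well_id, channel) at line(s) ",
         paste(line_no[dup], collapse = ", "), call. = FALSE)
  if (is.null(tab$droplet_volume_nl)) tab$droplet_volume_nl <- 0.85
  tab$low_droplets <- tab$n_total < min_droplets
  tab
}

#' Write a plate table in the package CSV dialect
#'
#' @param plate Plate data frame ([read_plate()] layout or
#'   `generate_study()$plate`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  cols <- c(PLATE_COLUMNS, "droplet_volume_nl")
  cols <- cols[cols %in% names(plate)]
  utils::write.csv(plate[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt <- function(x, paper) {
  if (!is.numeric(x)) return(as.character(x))
  if (paper) formatC(x, format = "f", digits = 2) else
    formatC(x, format = "g", digits = 15)
}

#' Write an analysis report table
#'
#' Renders calibration, quantification or validation results as a delimited
#' table with deterministic column order. In `"paper"` mode numbers are
#' rendered at two decimals and `not_detected` samples print `0`; `"machine"`
#' mode keeps full precision.
#'
#' @param results A `"k_calibration"`, a list of `"quant_result"`, or a data
#'   frame.
#' @param path Output path (CSV).
#' @param format `"machine"` or `"paper"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("machine", "paper")) {
  format <- match.arg(format)
  paper <- format == "paper"
  if (inherits(results, "k_calibration")) {
    tab <- results$points
    tab$k_mean <- results$k_mean
    tab$rsd_pct <- results$k_rsd_pct
  } else if (is.list(results) && length(results) &&
             all(vapply(results, inherits, logical(1), "quant_result"))) {
    tab <- do.call(rbind, lapply(results, function(q) {
      meas <- q$trout_fraction_pct
      if (paper && q$call == "not_detected") meas <- 0
      data.frame(sample_id = q$sample_id,
                 trout_fraction_pct = meas,
                 replicate_sd = q$replicate_sd, rsd_pct = q$rsd_pct,
                 call = q$call, stringsAsFactors = FALSE)
    }))
  } else if (is.data.frame(results)) {
    tab <- results
  } else stop("unsupported results object", call. = FALSE)
  out <- as.data.frame(lapply(tab, .fmt, paper = paper),
                       stringsAsFactors = FALSE)
  names(out) <- names(tab)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration holding assay definitions, the K source (a fixed value
#' or a calibration CSV), LOD/LOQ thresholds, simulator parameters, the
#' random seed and the output directory. Exactly one K source must resolve.
#'
#' @param path Path to the YAML file.
#' @return Named list; `k` is resolved to a numeric value, assay entries are
#'   converted to [ddpcr_assay()] objects under `$assays`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_val <- !is.null(cfg$k_value)
  has_file <- !is.null(cfg$k_calibration_file)
  if (has_val == has_file)
    stop("config must set exactly one of k_value / k_calibration_file",
         call. = FALSE)
  if (has_val) {
    cfg$k <- as.numeric(cfg$k_value)
  } else {
    cal <- utils::read.csv(cfg$k_calibration_file, stringsAsFactors = FALSE)
    cfg$k <- estimate_K(cal)$k_mean
  }
  if (is.null(cfg$lod_pct)) cfg$lod_pct <- 0.2
  if (is.null(cfg$loq_max_abs_deviation)) cfg$loq_max_abs_deviation <- 25
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.null(cfg$assays)) {
    cfg$assays <- lapply(cfg$assays, function(a)
      ddpcr_assay(a$species_label, a$gene, a$accession, a$fwd_primer,
                  a$rev_primer, a$probe, a$reporter_dye,
                  if (is.null(a$expected_amplicon_bp)) NA_integer_
                  else a$expected_amplicon_bp))
  }
  cfg
}

#' Write a run log
#'
#' Records the configuration hash, the seed and the package version, so
#' every command-line run is traceable.
#'
#' @param path Log file path.
#' @param config Resolved configuration list.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, config) {
  hash <- sum(utf8ToInt(paste(utils::capture.output(utils::str(config)),
                              collapse = "\n"))) %% 1e9
  lines <- c(sprintf("salmoquant %s",
                     as.character(utils::packageVersion("salmoquant"))),
             sprintf("config_hash: %09.0f", hash),
             sprintf("seed: %s", config$seed),
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(lines, path)
  invisible(path)
}
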
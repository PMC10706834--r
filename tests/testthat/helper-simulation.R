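# Shared fixture builders for simulated studies.

# Reduce a simulated study to per-sample calibration points
# (replicate-mean concentrations per channel + the known fraction).
study_to_points <- function(st) {
  plate <- st$plate
  out <- lapply(split(plate, plate$sample_id), function(d) {
    qs <- sapply(c("FAM", "HEX"), function(ch) {
      rows <- d[d$channel == ch, ]
      mean(mapply(function(nt, np, v) {
        estimate_concentration(well_reading("w", d$sample_id[1], ch, nt, np,
                                            v))$copies_per_ul
      }, rows$n_total, rows$n_positive, rows$droplet_volume_nl))
    })
    f <- st$design$trout_mass_fraction_pct[
      st$design$sample_id == d$sample_id[1]]
    data.frame(trout_mass_fraction_pct = f, q_o = qs[["FAM"]],
               q_s = qs[["HEX"]])
  })
  pts <- do.call(rbind, out)
  pts[order(pts$trout_mass_fraction_pct), ]
}

published_table <- function(name) {
  utils::read.csv(system.file("extdata", paste0("published_", name, ".csv"),
                              package = "salmoquant"))
}
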
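# Shared fixture builders. Everything is generated in code at test time.

# Minimal screen cell table built directly (no simulation): `n` cells per
# (well, drug, time, pathway) row spec.
make_cells <- function(spec, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    z <- rnorm(r$n, mean = r$shift)
    data.frame(well = r$well, drug = r$drug, time = r$time,
               clone = r$pathway, pathway = r$pathway, mode = r$mode,
               readout_ratio = if (r$mode == "ratio")
                 0.2 + 3.8 * plogis(z) else NA_real_,
               readout_nuclear = if (r$mode == "nuclear_intensity")
                 100 * exp(0.4 * z) else NA_real_,
               cell_area = rlnorm(r$n, log(650), 0.3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

cells_spec <- function(well, drug, time, pathway, mode = "ratio",
                       n = 50, shift = 0) {
  expand.grid(well = well, drug = drug, time = time, pathway = pathway,
              mode = mode, n = n, shift = shift,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# A small screen design that keeps unit tests fast; any screen_design()
# argument can be overridden.
small_design <- function(...) {
  args <- list(n_pos = 6, n_neg = 6, n_idio = 3, n_dmso_wells = 6,
               wells_per_drug = 2, timepoints = c(0, 24, 48),
               cells_per_well = 60)
  user <- list(...)
  args[names(user)] <- user
  do.call(screen_design, args)
}

# Brute-force two-sample KS oracle: scan every observed value.
ks_brute <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), 0)
  fy <- vapply(grid, function(g) mean(y <= g), 0)
  max(abs(fx - fy))
}

# One-clone noiseless image set (used by segmentation/feature tests).
one_clone_set <- function(localization = "nuclear", n_cells = 6,
                          seed = 42, noise = 0, shape = c(256, 256)) {
  panel <- barcode_panel(fluorophores = "CFP",
                         localizations = c("whole_cell", "cytoplasmic",
                                           "nuclear", "peroxisome", "er"),
                         barcodes = data.frame(fluorophore = "CFP",
                                               localization = localization))
  simulate_barcode_images(panel, n_cells_per_clone = n_cells,
                          image_shape = shape, noise = noise, seed = seed)
}
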
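# Shared fixtures: a small fast grid for unit tests and a noise-free variant.

fast_config <- function(...) {
  study_config(grid_nrow = 120, grid_ncol = 120, core_diameter_px = 14, ...)
}

noise_free_config <- function(...) {
  fast_config(suppression_cv = 0, spray_drift_amplitude = 0,
              pixel_noise_cv = 0, baseline_intensity = 0, ...)
}

# Hand-built 2x2 concentration image + masks with a single ROI covering
# given values, for direct-arithmetic summary checks.
tiny_conc_image <- function(values, lod = 0) {
  n <- length(values)
  conc <- matrix(values, 1, n)
  censor <- matrix(ifelse(values < lod, "below_lod", "quantified"), 1, n)
  conc[values < lod] <- lod / 2
  structure(list(conc = conc, censor = censor, lod_conc = lod,
                 substitution = lod / 2, normalized = TRUE),
            class = "concentration_image")
}

tiny_masks <- function(n) {
  roi_masks(matrix(1L, 1, n),
            tibble::tibble(label = c(0L, 1L),
                           roi = c("background", "blob"),
                           role = c("background", "tissue_region"),
                           level_ugg = c(NA, NA)))
}
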
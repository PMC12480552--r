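# Synthetic study generator: seeded MSI sections with a mimetic calibration
# array, ROI masks, a ground-truth bundle, and animal-level bioanalysis tables.
# The defaults emulate the mouse brain-metastasis (BM) study conditions:
# region means of ~1700 ng/g (tumor), ~1860 ng/g (ventricle) and a whole-section
# mean of ~487 ng/g, a 12-level mimetic model (0.1-100 ug/g plus blank), and an
# internal-standard coating of ~3 ug/g with spray drift.

#' Study configuration for the synthetic MSI + bioanalysis generator
#'
#' Bundles every tunable of the synthetic study: imaging grid, region truth
#' concentrations, mimetic-model calibration levels, internal-standard (IS)
#' level, noise/suppression/drift parameters, animal-group structure for the
#' bioanalysis tables, protein-binding fractions and assay limits. The
#' defaults describe a mouse brain-metastasis study arm dosed with a
#' brain-penetrant PARP inhibitor.
#'
#' @param grid_nrow,grid_ncol Image grid size in pixels.
#' @param pixel_size_um Pixel edge length in micrometers (default 75).
#' @param treatments Character vector of treatment labels.
#' @param dose_mg_per_kg Nominal dose, metadata only.
#' @param group_params Data frame with one row per animal group: `group`,
#'   `n_animals`, `plasma_median` (ng/mL), `brain_median` (ng/g),
#'   `tumor_median` (ng/g or `NA`), `has_tumor` (logical; whether MSI sections
#'   from this group contain a tumor region).
#' @param geometric_sd Geometric standard deviation of the lognormal
#'   inter-animal variability (applies to plasma, brain and tumor draws).
#' @param region_true_conc Named numeric vector of true tissue concentrations
#'   in ng/g for the non-parenchyma regions (default `tumor = 1700`,
#'   `ventricle = 1860`).
#' @param whole_section_mean Target whole-section mean in ng/g for a
#'   tumor-bearing section; the parenchyma truth level is solved from this and
#'   the region geometry (default 487).
#' @param calibration_levels Nominal mimetic-model levels in ug/g. A blank
#'   (0 ug/g) core is always added.
#' @param is_nominal_conc IS tissue-equivalent concentration in ug/g
#'   (default 3).
#' @param response_analyte,response_is Instrument response factors in counts
#'   per ug/g for the analyte and IS channels.
#' @param suppression_cv Coefficient of variation of the multiplicative ion
#'   suppression field shared by both channels (fraction; 0 disables).
#' @param suppression_scale Correlation scale of the suppression field in
#'   pixels.
#' @param spray_drift_amplitude Relative amplitude of the linear IS spray
#'   drift gradient along x (fraction; 0 disables).
#' @param pixel_noise_cv Per-pixel multiplicative lognormal noise CV applied
#'   independently to each channel (fraction).
#' @param baseline_intensity Mean additive chemical-noise baseline on the
#'   analyte channel, in counts (0 disables; gives the blank core a nonzero
#'   limit of blank).
#' @param baseline_cv CV of the baseline noise.
#' @param fu_brain,fu_plasma Unbound fractions in brain and plasma, in (0, 1].
#' @param homogenate_dilution Added-volume:tissue-weight ratio used for brain
#'   homogenates (default 4, i.e. 1:4 w:v, a 5x dilution).
#' @param lloq Named numeric vector of bioanalysis lower limits of
#'   quantification in ng/mL (names `plasma`, `brain_homogenate`, `csf`).
#' @param lod_override Optional externally determined MSI limit of detection
#'   in ng/g, honored verbatim during censoring (e.g. a value validated on a
#'   separate instrument run); `NULL` estimates the LOD from the blank core.
#' @param n_planes Number of section planes per animal in pipeline runs.
#' @param core_diameter_px Diameter of each mimetic-model core in pixels.
#' @param analyte_mz,is_mz m/z metadata for the two channels.
#'
#' @return An object of class `study_config` (a validated list).
#' @export
study_config <- function(grid_nrow = 200,
                         grid_ncol = 200,
                         pixel_size_um = 75,
                         treatments = "niraparib",
                         dose_mg_per_kg = 35,
                         group_params = NULL,
                         geometric_sd = 1.2,
                         region_true_conc = c(tumor = 1700, ventricle = 1860),
                         whole_section_mean = 487,
                         calibration_levels = c(0.1, 0.2, 0.3, 0.5, 1,
                                                5, 10, 25, 50, 75, 100),
                         is_nominal_conc = 3,
                         response_analyte = 1500,
                         response_is = 1200,
                         suppression_cv = 0.20,
                         suppression_scale = 40,
                         spray_drift_amplitude = 0.15,
                         pixel_noise_cv = 0.10,
                         baseline_intensity = 10,
                         baseline_cv = 0.30,
                         fu_brain = 0.07,
                         fu_plasma = 0.50,
                         homogenate_dilution = 4,
                         lloq = c(plasma = 2, brain_homogenate = 2, csf = 2),
                         lod_override = NULL,
                         n_planes = 5,
                         core_diameter_px = 20,
                         analyte_mz = 321.1710,
                         is_mz = 328.2149) {
  if (is.null(group_params)) {
    group_params <- tibble::tibble(
      group         = c("BM", "no-BM"),
      n_animals     = c(4L, 3L),
      plasma_median = c(2535, 3847),
      brain_median  = c(543, 658),
      tumor_median  = c(NA_real_, NA_real_),
      has_tumor     = c(TRUE, FALSE)
    )
  }
  group_params <- tibble::as_tibble(group_params)
  needed <- c("group", "n_animals", "plasma_median", "brain_median",
              "tumor_median", "has_tumor")
  if (!all(needed %in% names(group_params))) {
    stop_msikp("`group_params` is missing required columns",
               "msikp_config_error")
  }
  if (any(group_params$n_animals < 1) ||
      any(!is.finite(group_params$plasma_median) |
          group_params$plasma_median <= 0) ||
      any(!is.finite(group_params$brain_median) |
          group_params$brain_median <= 0)) {
    stop_msikp("group medians must be positive and n_animals >= 1",
               "msikp_config_error")
  }

  check_scalar_number(grid_nrow, "grid_nrow", min = 40)
  check_scalar_number(grid_ncol, "grid_ncol", min = 40)
  check_scalar_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  check_scalar_number(geometric_sd, "geometric_sd", min = 1)
  check_scalar_number(is_nominal_conc, "is_nominal_conc", min = 0,
                      strict_min = TRUE)
  check_scalar_number(suppression_cv, "suppression_cv", min = 0)
  check_scalar_number(spray_drift_amplitude, "spray_drift_amplitude",
                      min = 0, max = 0.95)
  check_scalar_number(pixel_noise_cv, "pixel_noise_cv", min = 0)
  check_scalar_number(baseline_intensity, "baseline_intensity", min = 0)
  check_scalar_number(fu_brain, "fu_brain", min = 0, max = 1,
                      strict_min = TRUE)
  check_scalar_number(fu_plasma, "fu_plasma", min = 0, max = 1,
                      strict_min = TRUE)
  check_scalar_number(homogenate_dilution, "homogenate_dilution", min = 0)
  check_scalar_number(whole_section_mean, "whole_section_mean", min = 0,
                      strict_min = TRUE)

  if (any(!is.finite(region_true_conc) | region_true_conc < 0)) {
    stop_msikp("`region_true_conc` values must be non-negative",
               "msikp_config_error")
  }
  if (any(calibration_levels <= 0) ||
      anyDuplicated(calibration_levels) > 0) {
    stop_msikp("`calibration_levels` must be strictly positive and distinct",
               "msikp_config_error")
  }
  if (!is.null(lod_override)) {
    check_scalar_number(lod_override, "lod_override", min = 0)
  }

  cfg <- list(
    grid_nrow = as.integer(grid_nrow), grid_ncol = as.integer(grid_ncol),
    pixel_size_um = pixel_size_um,
    treatments = treatments, dose_mg_per_kg = dose_mg_per_kg,
    group_params = group_params, geometric_sd = geometric_sd,
    region_true_conc = region_true_conc,
    whole_section_mean = whole_section_mean,
    calibration_levels = sort(calibration_levels),
    is_nominal_conc = is_nominal_conc,
    response_analyte = response_analyte, response_is = response_is,
    suppression_cv = suppression_cv, suppression_scale = suppression_scale,
    spray_drift_amplitude = spray_drift_amplitude,
    pixel_noise_cv = pixel_noise_cv,
    baseline_intensity = baseline_intensity, baseline_cv = baseline_cv,
    fu_brain = fu_brain, fu_plasma = fu_plasma,
    homogenate_dilution = homogenate_dilution,
    lloq = lloq, lod_override = lod_override,
    n_planes = as.integer(n_planes),
    core_diameter_px = core_diameter_px,
    analyte_mz = analyte_mz, is_mz = is_mz
  )
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  grid: %d x %d px @ %g um\n",
              x$grid_nrow, x$grid_ncol, x$pixel_size_um))
  cat(sprintf("  regions (ng/g): %s; whole-section target %g\n",
              paste(names(x$region_true_conc), x$region_true_conc,
                    sep = "=", collapse = ", "),
              x$whole_section_mean))
  cat(sprintf("  calibration: %d levels (%g-%g ug/g) + blank; IS %g ug/g\n",
              length(x$calibration_levels), min(x$calibration_levels),
              max(x$calibration_levels), x$is_nominal_conc))
  cat(sprintf("  noise: suppression CV %g (scale %g px), drift %g, pixel CV %g\n",
              x$suppression_cv, x$suppression_scale,
              x$spray_drift_amplitude, x$pixel_noise_cv))
  cat(sprintf("  groups: %s\n",
              paste(x$group_params$group, x$group_params$n_animals,
                    sep = " n=", collapse = "; ")))
  invisible(x)
}

# ---- geometry -------------------------------------------------------------

ellipse_mask <- function(nrow, ncol, center, radii) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((cc - center[2]) / radii[2])^2 <= 1
}

# Procedural section geometry: a tissue ellipse holding a ventricle and
# (optionally) two tumor foci, with the mimetic-model cores in two rows of six
# below the tissue. Labels: 0 background, 1 parenchyma, 2 ventricle, 3 tumor,
# 100 blank core, 100 + i the i-th calibration level (ascending).
build_section_masks <- function(config, include_tumor = TRUE) {
  nr <- config$grid_nrow
  nc <- config$grid_ncol
  lab <- matrix(0L, nr, nc)

  tissue <- ellipse_mask(nr, nc, c(0.39 * nr, 0.50 * nc),
                         c(0.275 * nr, 0.40 * nc))
  lab[tissue] <- 1L

  regions <- names(config$region_true_conc)
  known <- c("tumor", "ventricle", "parenchyma")
  if (!all(regions %in% known)) {
    stop_msikp(sprintf(
      "no geometry template for region(s): %s",
      paste(setdiff(regions, known), collapse = ", ")),
      "msikp_config_error")
  }

  if ("ventricle" %in% regions) {
    vent <- ellipse_mask(nr, nc, c(0.33 * nr, 0.50 * nc),
                         c(0.035 * nr, 0.09 * nc)) & tissue
    lab[vent] <- 2L
  }
  if (include_tumor && "tumor" %in% regions) {
    tum <- (ellipse_mask(nr, nc, c(0.47 * nr, 0.67 * nc),
                         c(0.050 * nr, 0.045 * nc)) |
            ellipse_mask(nr, nc, c(0.30 * nr, 0.32 * nc),
                         c(0.040 * nr, 0.035 * nc))) & tissue
    lab[tum] <- 3L
  }

  # cores: blank first, then ascending levels, two rows of six
  levels <- config$calibration_levels
  n_cores <- length(levels) + 1L
  per_row <- ceiling(n_cores / 2)
  radius <- config$core_diameter_px / 2
  row_y <- c(0.755, 0.890) * nr
  xs <- seq(0.09 * nc, 0.91 * nc, length.out = per_row)
  core_labels <- integer(0)
  for (i in seq_len(n_cores)) {
    ri <- if (i <= per_row) 1 else 2
    ci <- if (i <= per_row) i else i - per_row
    core <- ellipse_mask(nr, nc, c(row_y[ri], xs[ci]), c(radius, radius))
    lab_i <- if (i == 1) 100L else 100L + (i - 1L)
    lab[core & lab == 0L] <- lab_i
    core_labels <- c(core_labels, lab_i)
  }

  label_map <- tibble::tibble(
    label = c(0L, 1L, 2L, 3L, core_labels),
    roi = c("background", "parenchyma", "ventricle", "tumor",
            "core_blank", paste0("core_", levels)),
    role = c("background", "tissue_region", "tissue_region", "tissue_region",
             "core_blank", rep("core_level", length(levels))),
    level_ugg = c(NA, NA, NA, NA, 0, levels)
  )
  label_map <- label_map[label_map$label %in% c(0L, unique(as.vector(lab))), ]
  roi_masks(lab, label_map)
}

# ---- MSI dataset ----------------------------------------------------------

# Smoothed lognormal multiplicative field with mean ~1 and the requested CV:
# white Gaussian noise on a coarse grid, bilinearly interpolated to the full
# grid, restandardized, then exponentiated.
smooth_lognormal_field <- function(nrow, ncol, scale, cv) {
  if (cv <= 0) {
    return(matrix(1, nrow, ncol))
  }
  gr <- ceiling(nrow / scale) + 2L
  gc <- ceiling(ncol / scale) + 2L
  g <- matrix(rnorm(gr * gc), gr, gc)
  rpos <- (seq_len(nrow) - 1) / scale + 1
  cpos <- (seq_len(ncol) - 1) / scale + 1
  r0 <- pmin(floor(rpos), gr - 1L); rf <- rpos - r0
  c0 <- pmin(floor(cpos), gc - 1L); cf <- cpos - c0
  # bilinear interpolation, vectorized over the full grid
  f00 <- g[cbind(rep(r0, ncol), rep(c0, each = nrow))]
  f10 <- g[cbind(rep(r0 + 1L, ncol), rep(c0, each = nrow))]
  f01 <- g[cbind(rep(r0, ncol), rep(c0 + 1L, each = nrow))]
  f11 <- g[cbind(rep(r0 + 1L, ncol), rep(c0 + 1L, each = nrow))]
  wr <- rep(rf, ncol); wc <- rep(cf, each = nrow)
  z <- (1 - wr) * (1 - wc) * f00 + wr * (1 - wc) * f10 +
       (1 - wr) * wc * f01 + wr * wc * f11
  z <- (z - mean(z)) / sd(z)
  sdlog <- sqrt(log(1 + cv^2))
  matrix(exp(sdlog * z - sdlog^2 / 2), nrow, ncol)
}

#' Generate a synthetic two-channel MSI section with calibration cores
#'
#' Builds one simulated tissue section plus on-slide mimetic-model calibration
#' array. The analyte channel is `response * true_conc * suppression * noise`
#' plus an additive chemical-noise baseline; the IS channel is
#' `response * is_level * suppression * drift * noise`, where the suppression
#' field is shared between channels (so the analyte/IS ratio cancels it) and
#' the spray-drift gradient acts on the IS channel only.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed; expanded into independent per-component
#'   substreams so the draw for one component does not perturb the others.
#' @param include_tumor Whether the section carries tumor foci (a BM-group
#'   section) or not.
#'
#' @return A list with elements `dataset` (class `msi_dataset`), `masks`
#'   (class `roi_masks`) and `truth` (class `ground_truth`).
#' @export
generate_msi_dataset <- function(config, seed, include_tumor = TRUE) {
  stopifnot(inherits(config, "study_config"))
  masks <- build_section_masks(config, include_tumor = include_tumor)
  nr <- config$grid_nrow
  nc <- config$grid_ncol
  lab <- masks$label_image
  map <- masks$label_map

  # truth map (ng/g): parenchyma level solved so that a tumor-bearing section
  # averages `whole_section_mean` over the tissue ROI
  bm_masks <- if (include_tumor) masks else build_section_masks(config, TRUE)
  bm_lab <- bm_masks$label_image
  tissue_n <- sum(bm_lab %in% 1:3)
  other <- 0
  for (rg in names(config$region_true_conc)) {
    l <- bm_masks$label_map$label[bm_masks$label_map$roi == rg]
    if (length(l)) other <- other + config$region_true_conc[[rg]] * sum(bm_lab == l)
  }
  par_n <- sum(bm_lab == 1L)
  parenchyma_conc <- (config$whole_section_mean * tissue_n - other) / par_n
  if (parenchyma_conc < 0) {
    stop_msikp("whole_section_mean is too low for the configured region truth",
               "msikp_config_error")
  }

  true_conc <- matrix(0, nr, nc)
  true_conc[lab == 1L] <- parenchyma_conc
  for (rg in names(config$region_true_conc)) {
    l <- map$label[map$roi == rg]
    if (length(l)) true_conc[lab == l] <- config$region_true_conc[[rg]]
  }
  for (i in which(map$role == "core_level")) {
    true_conc[lab == map$label[i]] <- map$level_ugg[i] * 1000
  }

  n <- nr * nc
  set.seed(substream_seed(seed, "suppression"))
  supp <- smooth_lognormal_field(nr, nc, config$suppression_scale,
                                 config$suppression_cv)
  drift <- matrix(1 + config$spray_drift_amplitude *
                    (2 * (rep(seq_len(nc), each = nr) - 1) / (nc - 1) - 1),
                  nr, nc)
  set.seed(substream_seed(seed, "noise_analyte"))
  n_a <- matrix(rlnorm_cv(n, config$pixel_noise_cv), nr, nc)
  set.seed(substream_seed(seed, "noise_is"))
  n_is <- matrix(rlnorm_cv(n, config$pixel_noise_cv), nr, nc)
  set.seed(substream_seed(seed, "baseline"))
  base <- config$baseline_intensity *
    matrix(rlnorm_cv(n, config$baseline_cv), nr, nc)

  analyte <- config$response_analyte * (true_conc / 1000) * supp * n_a + base
  is_ch <- config$response_is * config$is_nominal_conc * supp * drift * n_is

  dataset <- msi_dataset(analyte, is_ch,
                         pixel_size_um = config$pixel_size_um,
                         analyte_mz = config$analyte_mz,
                         is_mz = config$is_mz)
  truth <- structure(list(
    true_conc_map = true_conc,
    suppression_field = supp,
    drift_field = drift,
    is_true_map = matrix(config$is_nominal_conc, nr, nc),
    parenchyma_conc = parenchyma_conc,
    seed = seed,
    config_snapshot = config
  ), class = "ground_truth")

  list(dataset = dataset, masks = masks, truth = truth)
}

#' Exact per-ROI means of the ground-truth concentration map
#'
#' The oracle for recovery tests: averages the true (noise-free) concentration
#' map over each ROI of the mask set.
#'
#' @param truth A `ground_truth` bundle from [generate_msi_dataset()].
#' @param masks The matching `roi_masks`.
#' @return A tibble with `roi`, `n_pixels`, `true_mean` (ng/g), including the
#'   whole-tissue union ROI `"tissue"`.
#' @export
truth_report <- function(truth, masks) {
  stopifnot(inherits(truth, "ground_truth"), inherits(masks, "roi_masks"))
  if (!all(dim(truth$true_conc_map) == dim(masks$label_image))) {
    stop_msikp("ground truth and masks are on different grids",
               "msikp_dimension_error")
  }
  rois <- c("tissue", setdiff(masks$label_map$roi, "background"))
  rows <- lapply(rois, function(r) {
    px <- roi_pixels(masks, r)
    tibble::tibble(roi = r, n_pixels = sum(px),
                   true_mean = mean(truth$true_conc_map[px]))
  })
  dplyr::bind_rows(rows)
}

# ---- bioanalysis tables ---------------------------------------------------

#' Generate a synthetic animal-level bioanalysis table
#'
#' Draws per-animal steady-state concentrations lognormally around the
#' configured group medians (plasma in ng/mL, brain and tumor tissue in ng/g),
#' derives the measured brain-homogenate concentration through the configured
#' w:v dilution (1 g tissue ~ 1 mL), and censors values below the LLOQ:
#' censored entries carry the applicable LLOQ itself with `*_bql = TRUE`,
#' never a fabricated number.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed.
#' @return A tibble with one row per animal: identifiers, matrix
#'   concentrations and per-matrix BQL flags.
#' @export
generate_bioanalysis_table <- function(config, seed) {
  stopifnot(inherits(config, "study_config"))
  gsd <- config$geometric_sd
  sdlog <- log(gsd)
  dil <- config$homogenate_dilution
  lloq_pl <- config$lloq[["plasma"]]
  lloq_bh <- config$lloq[["brain_homogenate"]]
  rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(config$group_params))) {
    gp <- config$group_params[g, ]
    set.seed(substream_seed(seed, paste0("bioanalysis_", gp$group)))
    for (a in seq_len(gp$n_animals)) {
      idx <- idx + 1L
      plasma <- rlnorm(1, log(gp$plasma_median), sdlog)
      brain <- rlnorm(1, log(gp$brain_median), sdlog)
      tumor <- if (is.finite(gp$tumor_median)) {
        rlnorm(1, log(gp$tumor_median), sdlog)
      } else {
        NA_real_
      }
      homog <- brain / (1 + dil)
      plasma_bql <- plasma < lloq_pl
      brain_bql <- homog < lloq_bh
      tumor_lloq_tissue <- lloq_bh * (1 + dil)
      tumor_bql <- is.finite(tumor) && tumor < tumor_lloq_tissue
      rows[[idx]] <- tibble::tibble(
        animal_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", gp$group), a),
        group = gp$group,
        treatment = config$treatments[[1]],
        plasma_conc = if (plasma_bql) lloq_pl else plasma,
        plasma_bql = plasma_bql,
        brain_homogenate_conc = if (brain_bql) lloq_bh else homog,
        brain_tissue_conc = if (brain_bql) lloq_bh * (1 + dil) else brain,
        brain_bql = brain_bql,
        tumor_conc = if (isTRUE(tumor_bql)) tumor_lloq_tissue else tumor,
        tumor_bql = tumor_bql
      )
    }
  }
  dplyr::bind_rows(rows)
}
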
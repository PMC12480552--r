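# Quantitative MSI workflow: channel extraction, LOB/LOD estimation, the
# conditional internal-standard normalization rule, mimetic-model calibration,
# per-pixel back-calculation and ROI aggregation.

#' Extract an intensity image from per-pixel peak lists
#'
#' Sums, for every pixel, the intensities of all centroided peaks whose m/z
#' falls inside a ppm window around the target. The window is interpreted as a
#' total width: `[target * (1 - w/2 * 1e-6), target * (1 + w/2 * 1e-6)]`, so
#' the conventional 2-ppm export is +/- 1 ppm.
#'
#' @param peak_lists List of per-pixel peak lists in column-major pixel order;
#'   each element a data frame with columns `mz` (sorted ascending) and
#'   `intensity`, or `NULL` for an empty pixel.
#' @param target_mz Target m/z.
#' @param window_ppm Total window width in ppm (default 2).
#' @param dim Integer vector `c(nrow, ncol)` of the image grid.
#' @return A numeric intensity matrix; pixels with no matching peak are 0.
#' @export
extract_channel <- function(peak_lists, target_mz, window_ppm = 2, dim) {
  stopifnot(length(dim) == 2, length(peak_lists) == prod(dim))
  if (window_ppm <= 0) {
    stop_msikp("`window_ppm` must be positive", "msikp_input_error")
  }
  lower <- target_mz * (1 - window_ppm / 2 * 1e-6)
  upper <- target_mz * (1 + window_ppm / 2 * 1e-6)
  vals <- vapply(peak_lists, function(pk) {
    if (is.null(pk) || nrow(pk) == 0) {
      return(0)
    }
    if (is.unsorted(pk$mz)) {
      stop_msikp("peak lists must be sorted by m/z", "msikp_input_error")
    }
    hit <- pk$mz >= lower & pk$mz <= upper
    sum(pk$intensity[hit])
  }, numeric(1))
  matrix(vals, dim[1], dim[2])
}

#' Estimate the limit of blank and limit of detection
#'
#' LOB is the highest signal expected from a blank:
#' `mean(blank) + z(1 - alpha) * sd(blank)` (z = 1.645 at the default
#' alpha = 0.05). The LOD, in the concentration units of the calibration
#' line, is the concentration whose expected signal exceeds the LOB by
#' `z * sd` of the lowest calibration level:
#' `lod = (lob + z * sd(low) - intercept) / slope`, clipped at 0.
#'
#' @param blank_values Blank-ROI pixel values (intensities or ratios; at
#'   least 30 pixels).
#' @param low_level_values Pixel values of the lowest calibration level (may
#'   be empty, in which case its SD is taken as 0).
#' @param alpha Upper tail probability (default 0.05).
#' @param slope,intercept Calibration line used to map the detection signal to
#'   concentration; with `slope = NULL` only the LOB is returned.
#' @return A list with `lob` (signal units), `lod_conc` (calibration
#'   concentration units, or `NA` without a slope), `alpha` and `z`.
#' @export
estimate_lob_lod <- function(blank_values, low_level_values = numeric(0),
                             alpha = 0.05, slope = NULL, intercept = 0) {
  if (length(blank_values) < 30) {
    stop_msikp("at least 30 blank pixels are required to estimate the LOB",
               "msikp_estimation_error")
  }
  z <- qnorm(1 - alpha)
  lob <- mean(blank_values) + z * sd(blank_values)
  lod <- NA_real_
  if (!is.null(slope)) {
    sd_low <- if (length(low_level_values) > 1) sd(low_level_values) else 0
    lod <- max(0, (lob + z * sd_low - intercept) / slope)
  }
  list(lob = lob, lod_conc = lod, alpha = alpha, z = z)
}

#' Decide whether to apply internal-standard normalization
#'
#' Pixel-by-pixel IS normalization is applied only if the whole-tissue ROI
#' signal is significantly above the blank-core ROI signal; normalizing a
#' tissue that carries no real analyte signal would only amplify noise into
#' artifactual distributions. The decision rule is a one-sided Welch test on
#' `log10(intensity + 1)` at level `alpha`, requiring the tissue mean to
#' exceed the blank mean. Degenerate zero-variance inputs fall back to exact
#' comparison of means.
#'
#' @param tissue_values,blank_values Raw analyte-channel intensities from the
#'   whole-tissue and blank-core ROIs.
#' @param alpha Test level (default 0.05).
#' @return A list of class `normalization_decision`: `normalize` (logical),
#'   `statistic`, `p_value`, `alpha`, `method`.
#' @export
decide_normalization <- function(tissue_values, blank_values, alpha = 0.05) {
  if (!length(tissue_values) || !length(blank_values)) {
    stop_msikp("both tissue and blank samples must be non-empty",
               "msikp_input_error")
  }
  lt <- log10(tissue_values + 1)
  lb <- log10(blank_values + 1)
  res <- tryCatch(
    t.test(lt, lb, alternative = "greater", var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # both samples essentially constant: exact comparison of means
    normalize <- mean(lt) > mean(lb)
    out <- list(normalize = normalize, statistic = NA_real_,
                p_value = if (normalize) 0 else 1,
                alpha = alpha, method = "exact comparison (zero variance)")
  } else {
    out <- list(normalize = unname(res$statistic) > 0 && res$p.value < alpha,
                statistic = unname(res$statistic),
                p_value = res$p.value, alpha = alpha,
                method = "one-sided Welch t on log10(intensity + 1)")
  }
  structure(out, class = "normalization_decision")
}

#' @export
print.normalization_decision <- function(x, ...) {
  cat(sprintf("<normalization_decision> normalize = %s (%s; p = %.3g, alpha = %g)\n",
              x$normalize, x$method, x$p_value, x$alpha))
  invisible(x)
}

#' Pixel-by-pixel internal-standard normalization
#'
#' Divides the analyte channel by the IS channel, substituting a positive
#' floor where the IS intensity falls below it (spray gaps would otherwise
#' blow the ratio up). The default floor is 1% of the median nonzero IS
#' intensity.
#'
#' @param analyte,is Intensity matrices on the same grid.
#' @param floor Positive IS floor; `NULL` uses the default rule.
#' @return A ratio matrix with attributes `normalized = TRUE` and
#'   `n_floor_substitutions`.
#' @export
normalize_pixels <- function(analyte, is, floor = NULL) {
  stopifnot(is.matrix(analyte), is.matrix(is), all(dim(analyte) == dim(is)))
  if (all(is == 0)) {
    stop_msikp("IS channel is entirely zero: spray failure, cannot normalize",
               "msikp_normalization_error")
  }
  if (is.null(floor)) {
    floor <- 0.01 * median(is[is > 0])
  }
  if (floor <= 0) {
    stop_msikp("`floor` must be positive", "msikp_input_error")
  }
  n_sub <- sum(is < floor)
  ratio <- analyte / pmax(is, floor)
  attr(ratio, "normalized") <- TRUE
  attr(ratio, "n_floor_substitutions") <- n_sub
  ratio
}

#' Extract the per-core pixel values of the mimetic calibration model
#'
#' @param image Intensity or ratio matrix (the same channel type that will be
#'   quantified).
#' @param masks A [roi_masks()] with core labels.
#' @return A list of class `calibration_series`: `levels` (ug/g, ascending),
#'   `values` (list of pixel-value vectors per level), `blank_values`, and
#'   `normalized` (taken from the image attribute).
#' @export
calibration_series <- function(image, masks) {
  stopifnot(inherits(masks, "roi_masks"))
  map <- masks$label_map
  lev_rows <- map[map$role == "core_level", ]
  lev_rows <- lev_rows[order(lev_rows$level_ugg), ]
  if (nrow(lev_rows) < 3) {
    stop_msikp("at least 3 non-blank calibration levels are required",
               "msikp_calibration_error")
  }
  values <- lapply(lev_rows$label, function(l) image[masks$label_image == l])
  blank_lab <- map$label[map$role == "core_blank"]
  blank_values <- if (length(blank_lab)) {
    image[masks$label_image == blank_lab]
  } else {
    numeric(0)
  }
  structure(list(levels = lev_rows$level_ugg, values = values,
                 blank_values = blank_values,
                 normalized = isTRUE(attr(image, "normalized"))),
            class = "calibration_series")
}

#' Fit the mimetic-model standard curve
#'
#' Weighted least-squares line of core response (mean analyte/IS ratio, or
#' mean raw intensity when unnormalized) against nominal spiked level. The
#' default weighting is 1/x, the bioanalytical convention for calibration
#' ranges spanning three orders of magnitude; ordinary least squares is
#' selectable. The blank core is excluded from the line but supplies the
#' limit of blank; the LOD is derived from the LOB and the lowest-level SD
#' via [estimate_lob_lod()].
#'
#' @param series A [calibration_series()].
#' @param weighting `"1/x"` (default) or `"ols"`.
#' @param per_pixel Fit on every core pixel instead of core means.
#' @param alpha Tail probability for the LOB/LOD (default 0.05).
#' @param r2_floor Minimum acceptable R^2 (default 0.90).
#' @param lod_override Optional externally determined LOD in ng/g, honored
#'   verbatim instead of the estimate.
#' @return An object of class `calibration_fit` with `slope` (response per
#'   ug/g), `intercept`, `r_squared`, `weighting`, `normalized`, `lob`
#'   (response units), `lod_conc` (ng/g), `levels_used`.
#' @export
fit_calibration <- function(series, weighting = c("1/x", "ols"),
                            per_pixel = FALSE, alpha = 0.05,
                            r2_floor = 0.90, lod_override = NULL) {
  stopifnot(inherits(series, "calibration_series"))
  weighting <- match.arg(weighting)
  keep <- lengths(series$values) > 0
  if (sum(keep) < 3) {
    stop_msikp("at least 3 non-blank levels with pixels are required",
               "msikp_calibration_error")
  }
  levels <- series$levels[keep]
  if (per_pixel) {
    x <- rep(levels, lengths(series$values[keep]))
    y <- unlist(series$values[keep])
  } else {
    x <- levels
    y <- vapply(series$values[keep], mean, numeric(1))
  }
  w <- if (weighting == "1/x") 1 / x else rep(1, length(x))
  fit <- lm(y ~ x, weights = w)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(slope) || slope <= 0 || r2 < r2_floor) {
    stop_msikp(sprintf(
      "calibration failure: slope = %.4g, R^2 = %.4f (floor %.2f)",
      slope, r2, r2_floor), "msikp_calibration_error")
  }
  ll <- estimate_lob_lod(series$blank_values,
                         series$values[keep][[1]],
                         alpha = alpha, slope = slope, intercept = intercept)
  lod_ng <- if (!is.null(lod_override)) lod_override else ll$lod_conc * 1000
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 weighting = weighting, normalized = series$normalized,
                 per_pixel = per_pixel,
                 lob = ll$lob, lod_conc = lod_ng,
                 lod_overridden = !is.null(lod_override),
                 levels_used = levels, alpha = alpha),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> slope %.4g / (ug/g), intercept %.4g, R^2 %.4f (%s, %s)\n",
    x$slope, x$intercept, x$r_squared, x$weighting,
    if (x$normalized) "IS-normalized" else "raw intensity"))
  cat(sprintf("  LOB %.4g (response units), LOD %.4g ng/g%s\n",
              x$lob, x$lod_conc,
              if (x$lod_overridden) " [override]" else ""))
  invisible(x)
}

#' Back-calculate a per-pixel concentration image
#'
#' Inverts the standard curve pixel by pixel:
#' `conc = (response - intercept) / slope`, clipping negatives at zero and
#' converting to ng/g. Pixels below the LOD are flagged and carry the
#' substitution value LOD/2; pixels outside the tissue and core ROIs (when
#' masks are given) are flagged off-tissue and carry `NA`.
#'
#' @param image The ratio or intensity matrix; its channel type (normalized
#'   or raw) must match the fit.
#' @param fit A [fit_calibration()] result.
#' @param masks Optional [roi_masks()] used to mark off-tissue pixels.
#' @return An object of class `concentration_image`: `conc` (ng/g), `censor`
#'   (character matrix: `"quantified"`, `"below_lod"`, `"off_tissue"`),
#'   `lod_conc`, `substitution`.
#' @export
quantify_image <- function(image, fit, masks = NULL) {
  stopifnot(inherits(fit, "calibration_fit"), is.matrix(image))
  img_norm <- isTRUE(attr(image, "normalized"))
  if (img_norm != fit$normalized) {
    stop_msikp(
      "image channel type (normalized/raw) does not match the calibration fit",
      "msikp_usage_error")
  }
  conc <- (image - fit$intercept) / fit$slope * 1000
  conc[conc < 0] <- 0
  censor <- matrix("quantified", nrow(image), ncol(image))
  lod <- fit$lod_conc
  sub <- lod / 2
  below <- conc < lod
  conc[below] <- sub
  censor[below] <- "below_lod"
  if (!is.null(masks)) {
    on_sample <- roi_pixels(masks, "tissue")
    for (r in masks$label_map$roi[masks$label_map$role %in%
                                  c("core_blank", "core_level")]) {
      on_sample <- on_sample | roi_pixels(masks, r)
    }
    conc[!on_sample] <- NA_real_
    censor[!on_sample] <- "off_tissue"
  }
  structure(list(conc = conc, censor = censor, lod_conc = lod,
                 substitution = sub, normalized = fit$normalized),
            class = "concentration_image")
}

#' @export
print.concentration_image <- function(x, ...) {
  q <- mean(x$censor == "quantified")
  cat(sprintf(
    "<concentration_image> %d x %d px, LOD %.4g ng/g, %.1f%% quantified\n",
    nrow(x$conc), ncol(x$conc), x$lod_conc, 100 * q))
  invisible(x)
}

#' Summarize a concentration image over one ROI
#'
#' Censored (below-LOD) pixels enter the statistics at the substitution value
#' LOD/2 by default; they can instead be excluded or set to zero. The policy
#' and the censored fraction are always reported.
#'
#' @param conc A [quantify_image()] result.
#' @param masks A [roi_masks()].
#' @param roi ROI name (see [roi_pixels()]).
#' @param censor_policy `"substitute"` (default), `"exclude"` or `"zero"`.
#' @return A one-row tibble: `roi`, `n_pixels`, `mean`, `sd`, `median`
#'   (ng/g), `fraction_censored`, `censor_policy`.
#' @export
summarize_roi <- function(conc, masks, roi,
                          censor_policy = c("substitute", "exclude", "zero")) {
  stopifnot(inherits(conc, "concentration_image"))
  censor_policy <- match.arg(censor_policy)
  px <- roi_pixels(masks, roi)
  vals <- conc$conc[px]
  cens <- conc$censor[px]
  keep <- cens != "off_tissue"
  vals <- vals[keep]
  cens <- cens[keep]
  if (!length(vals)) {
    stop_msikp(sprintf("ROI '%s' contains no on-sample pixels", roi),
               "msikp_summary_error")
  }
  frac_cens <- mean(cens == "below_lod")
  if (censor_policy == "exclude") {
    vals <- vals[cens != "below_lod"]
  } else if (censor_policy == "zero") {
    vals[cens == "below_lod"] <- 0
  }
  if (!length(vals)) {
    vals <- NA_real_
  }
  tibble::tibble(
    roi = roi, n_pixels = sum(keep),
    mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
    median = median(vals),
    fraction_censored = frac_cens, censor_policy = censor_policy
  )
}

#' Aggregate section-level ROI summaries to an animal mean
#'
#' Each section counts once, regardless of its pixel count: the animal value
#' is the unweighted mean of section means (the "mean of the mean
#' concentration measured from each tissue section" convention), with the SD
#' across sections.
#'
#' @param section_summaries A tibble of [summarize_roi()] rows for one ROI
#'   role across an animal's sections.
#' @return A one-row tibble: `roi`, `n_sections`, `mean`, `sd`.
#' @export
aggregate_animal <- function(section_summaries) {
  stopifnot(is.data.frame(section_summaries), nrow(section_summaries) >= 1)
  roi <- unique(section_summaries$roi)
  if (length(roi) != 1) {
    stop_msikp("section summaries mix ROI roles; aggregate one ROI at a time",
               "msikp_usage_error")
  }
  m <- section_summaries$mean
  tibble::tibble(roi = roi, n_sections = length(m), mean = mean(m),
                 sd = if (length(m) > 1) sd(m) else 0)
}
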
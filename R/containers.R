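# Core containers: the two-channel MSI pixel grid and the labeled ROI mask
# set. Images are base-R numeric matrices indexed [row, column], 1-based.

#' Two-channel MSI dataset
#'
#' @param analyte,is Numeric matrices of per-pixel ion intensities (arbitrary
#'   units) for the analyte and the stable-isotope-labeled internal standard.
#'   Must share dimensions; intensities must be finite and non-negative.
#' @param pixel_size_um Pixel edge length in micrometers.
#' @param analyte_mz,is_mz m/z metadata for the two extracted channels.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(analyte, is, pixel_size_um = 75,
                        analyte_mz = NA_real_, is_mz = NA_real_) {
  if (!is.matrix(analyte) || !is.matrix(is) ||
      !all(dim(analyte) == dim(is))) {
    stop_msikp("analyte and IS channels must be matrices on the same grid",
               "msikp_input_error")
  }
  if (any(!is.finite(analyte)) || any(!is.finite(is)) ||
      any(analyte < 0) || any(is < 0)) {
    stop_msikp("channel intensities must be finite and non-negative",
               "msikp_input_error")
  }
  structure(list(analyte = analyte, is = is,
                 pixel_size_um = pixel_size_um,
                 analyte_mz = analyte_mz, is_mz = is_mz),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d x %d px @ %g um, analyte m/z %.4f, IS m/z %.4f\n",
              nrow(x$analyte), ncol(x$analyte), x$pixel_size_um,
              x$analyte_mz, x$is_mz))
  invisible(x)
}

#' Labeled ROI mask set
#'
#' @param label_image Integer matrix of per-pixel labels.
#' @param label_map Data frame mapping `label` to `roi` (name), `role`
#'   (`"background"`, `"tissue_region"`, `"core_blank"`, `"core_level"`) and
#'   `level_ugg` (nominal mimetic-model level for cores, ug/g; blank = 0).
#' @return An object of class `roi_masks`.
#' @export
roi_masks <- function(label_image, label_map) {
  label_map <- tibble::as_tibble(label_map)
  stopifnot(is.matrix(label_image),
            all(c("label", "roi", "role", "level_ugg") %in% names(label_map)))
  if (sum(label_map$role == "core_blank") > 1) {
    stop_msikp("at most one blank-core label is allowed", "msikp_input_error")
  }
  unknown <- setdiff(unique(as.vector(label_image)), label_map$label)
  if (length(unknown)) {
    stop_msikp(sprintf("labels present in image but not in map: %s",
                       paste(unknown, collapse = ", ")),
               "msikp_input_error")
  }
  structure(list(label_image = label_image, label_map = label_map),
            class = "roi_masks")
}

#' @export
print.roi_masks <- function(x, ...) {
  cat(sprintf("<roi_masks> %d x %d px, %d labels: %s\n",
              nrow(x$label_image), ncol(x$label_image), nrow(x$label_map),
              paste(utils::head(x$label_map$roi, 8), collapse = ", ")))
  invisible(x)
}

#' Logical pixel mask for a named ROI
#'
#' `roi = "tissue"` returns the union of all tissue-region labels; any other
#' value must match a single `roi` name in the label map (e.g. `"tumor"`,
#' `"ventricle"`, `"core_blank"`, `"core_5"`, `"background"`).
#'
#' @param masks A [roi_masks()] object.
#' @param roi ROI name.
#' @return A logical matrix.
#' @export
roi_pixels <- function(masks, roi) {
  stopifnot(inherits(masks, "roi_masks"), is.character(roi), length(roi) == 1)
  map <- masks$label_map
  labels <- if (roi == "tissue") {
    map$label[map$role == "tissue_region"]
  } else {
    map$label[map$roi == roi]
  }
  if (!length(labels)) {
    stop_msikp(sprintf("ROI '%s' not found in mask set", roi),
               "msikp_roi_error")
  }
  matrix(masks$label_image %in% labels,
         nrow(masks$label_image), ncol(masks$label_image))
}
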
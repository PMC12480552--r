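# Orchestration: simulate -> quantify -> partition -> stats in one seeded,
# reproducible run, plus the ion-image rendering convention and report I/O.

#' Quantify one MSI section
#'
#' Applies the full quantification chain to a two-channel section with
#' calibration cores: the conditional IS-normalization decision (tissue vs
#' blank core), standard-curve fitting on the matching channel type,
#' per-pixel back-calculation, and ROI summaries for the whole tissue and
#' every labeled sub-region.
#'
#' @param dataset An [msi_dataset()].
#' @param masks The matching [roi_masks()] with core labels.
#' @param alpha Level for the normalization decision and LOB (default 0.05).
#' @param lod_override Optional externally determined LOD in ng/g.
#' @param censor_policy Censored-pixel policy for summaries (see
#'   [summarize_roi()]).
#' @param weighting Calibration weighting (see [fit_calibration()]).
#' @return A list: `fit`, `decision`, `conc` (a `concentration_image`),
#'   `summaries` (tibble, one row per ROI).
#' @export
quantify_section <- function(dataset, masks, alpha = 0.05,
                             lod_override = NULL,
                             censor_policy = "substitute",
                             weighting = "1/x") {
  stopifnot(inherits(dataset, "msi_dataset"), inherits(masks, "roi_masks"))
  tissue_px <- dataset$analyte[roi_pixels(masks, "tissue")]
  blank_px <- dataset$analyte[roi_pixels(masks, "core_blank")]
  decision <- decide_normalization(tissue_px, blank_px, alpha = alpha)
  image <- if (decision$normalize) {
    normalize_pixels(dataset$analyte, dataset$is)
  } else {
    dataset$analyte
  }
  series <- calibration_series(image, masks)
  fit <- fit_calibration(series, weighting = weighting, alpha = alpha,
                         lod_override = lod_override)
  conc <- quantify_image(image, fit, masks)
  rois <- c("tissue",
            masks$label_map$roi[masks$label_map$role == "tissue_region"])
  summaries <- dplyr::bind_rows(lapply(rois, function(r) {
    summarize_roi(conc, masks, r, censor_policy = censor_policy)
  }))
  list(fit = fit, decision = decision, conc = conc, summaries = summaries)
}

#' Run a full synthetic study end to end
#'
#' Generates the bioanalysis table and one MSI section per animal and plane,
#' quantifies every section, aggregates ROI concentrations per animal
#' (unweighted mean of section means), computes group partition coefficients
#' under the requested aggregation convention (Kp tumor from the MSI tumor
#' ROI versus terminal plasma), and fits the statistical layer (Welch test
#' between animal groups on whole-tissue section means, nested mixed model
#' with EMMs per region). Fully deterministic given `(config, seed)`.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed.
#' @param aggregation `"mean-of-ratios"` (default) or `"ratio-of-means"`.
#' @param out_dir Optional directory; when given, report tables are written
#'   as CSV plus a `manifest.json`.
#' @return An object of class `msikp_study_report`: `bioanalysis`,
#'   `section_summaries`, `animal_summaries`, `partition`, `welch`,
#'   `mixed_fit`, `emm`, `manifest`.
#' @export
run_study <- function(config = study_config(), seed = 1L,
                      aggregation = c("mean-of-ratios", "ratio-of-means"),
                      out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  aggregation <- match.arg(aggregation)

  bioanalysis <- generate_bioanalysis_table(config, seed)

  section_rows <- list()
  norm_decisions <- 0L
  for (g in seq_len(nrow(config$group_params))) {
    gp <- config$group_params[g, ]
    for (a in seq_len(gp$n_animals)) {
      animal_id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", gp$group), a)
      for (p in seq_len(config$n_planes)) {
        sec_seed <- substream_seed(
          seed, sprintf("msi_%s_%d_%d", gp$group, a, p))
        sec <- generate_msi_dataset(config, sec_seed,
                                    include_tumor = gp$has_tumor)
        q <- quantify_section(sec$dataset, sec$masks,
                              lod_override = config$lod_override)
        norm_decisions <- norm_decisions + as.integer(q$decision$normalize)
        s <- q$summaries
        s$animal_id <- animal_id
        s$group <- gp$group
        s$treatment <- config$treatments[[1]]
        s$plane <- p
        section_rows[[length(section_rows) + 1L]] <- s
      }
    }
  }
  section_summaries <- dplyr::bind_rows(section_rows)

  animal_summaries <- section_summaries |>
    dplyr::group_by(.data$animal_id, .data$group, .data$treatment,
                    .data$roi) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      mean = mean(.data$mean),
      sd = if (dplyr::n() > 1) sd(.data$mean) else 0,
      .groups = "drop"
    )

  # group partition coefficients; Kp tumor from the MSI tumor ROI (mean over
  # all tumor-containing sections) versus terminal plasma
  partition <- dplyr::bind_rows(lapply(
    split(bioanalysis, bioanalysis$group),
    function(rec) {
      res <- group_partition_summary(rec, fu_brain = config$fu_brain,
                                     fu_plasma = config$fu_plasma,
                                     method = aggregation)
      res$group <- rec$group[1]
      tum <- section_summaries[section_summaries$group == rec$group[1] &
                                 section_summaries$roi == "tumor", ]
      res$tumor_msi_mean <- if (nrow(tum)) mean(tum$mean) else NA_real_
      res$kp_tumor_msi <- if (nrow(tum) && !any(rec$plasma_bql)) {
        kp_tumor(mean(tum$mean), mean(rec$plasma_conc[!rec$plasma_bql]))
      } else {
        NA_real_
      }
      res
    }))
  partition <- dplyr::relocate(partition, "group")

  # statistical layer
  groups <- unique(section_summaries$group)
  welch <- NULL
  if (length(groups) == 2) {
    x <- section_summaries$mean[section_summaries$roi == "tissue" &
                                  section_summaries$group == groups[1]]
    y <- section_summaries$mean[section_summaries$roi == "tissue" &
                                  section_summaries$group == groups[2]]
    welch <- welch_t_test(x, y)
    welch$comparison <- paste(groups, collapse = " vs ")
  }
  region_sum <- section_summaries[section_summaries$roi != "tissue", ]
  region_sum$tumor_group <- region_sum$group
  obs <- section_observations(region_sum)
  mixed_fit <- fit_mixed_model(obs, design = "mouse-bm")
  emm <- estimated_marginal_means(mixed_fit, "roi")

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("msikp")),
    aggregation = aggregation,
    censor_policy = "substitute (LOD/2)",
    n_sections = nrow(section_summaries) /
      length(unique(section_summaries$roi)),
    n_normalized_sections = norm_decisions,
    lod_override = config$lod_override
  )

  report <- structure(list(
    bioanalysis = bioanalysis,
    section_summaries = section_summaries,
    animal_summaries = animal_summaries,
    partition = partition,
    welch = welch,
    mixed_fit = mixed_fit,
    emm = emm,
    manifest = manifest
  ), class = "msikp_study_report")

  if (!is.null(out_dir)) {
    write_study_report(report, out_dir)
  }
  report
}

#' @export
print.msikp_study_report <- function(x, ...) {
  cat("<msikp_study_report>\n")
  cat(sprintf("  %d animals, %d section summaries\n",
              nrow(x$bioanalysis), nrow(x$section_summaries)))
  print(x$partition[, c("group", "kp_brain", "kp_uu_brain", "kp_tumor_msi",
                        "aggregation", "status")])
  invisible(x)
}

#' Write the report bundle as CSV tables plus a JSON manifest
#'
#' @param report A [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "msikp_study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$bioanalysis, "bioanalysis.csv")
  wr(report$section_summaries, "section_summaries.csv")
  wr(report$animal_summaries, "animal_summaries.csv")
  part <- report$partition
  for (col in c("kp_brain", "kp_uu_brain", "kp_tumor", "kp_tumor_msi")) {
    part[[col]] <- round_report(part[[col]])
  }
  wr(part, "partition_group.csv")
  wr(report$emm, "emm_region.csv")
  if (!is.null(report$welch)) {
    wr(tibble::as_tibble(report$welch), "welch.csv")
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Partition coefficients from a table of group-mean concentrations
#'
#' Ratio-of-means arithmetic on published-style summary tables: given group
#' mean plasma (ng/mL), brain (ng/g) and optional tumor (ng/g)
#' concentrations, returns Kp brain and Kp tumor rounded to 3 decimals
#' (half away from zero), mirroring report-table formatting.
#'
#' @param group_means Data frame with columns `label`, `plasma`, `brain` and
#'   optionally `tumor`.
#' @return The input tibble with added `kp_brain` and `kp_tumor` columns.
#' @export
partition_from_means <- function(group_means) {
  gm <- tibble::as_tibble(group_means)
  stopifnot(all(c("label", "plasma", "brain") %in% names(gm)))
  gm$kp_brain <- round_report(kp_brain(gm$brain, gm$plasma))
  gm$kp_tumor <- if ("tumor" %in% names(gm)) {
    ifelse(is.finite(gm$tumor),
           round_report(kp_tumor(ifelse(is.finite(gm$tumor), gm$tumor, 0),
                                 gm$plasma)),
           NA_real_)
  } else {
    NA_real_
  }
  gm
}

#' Bundled example tables of published group-mean concentrations
#'
#' Plain-CSV transcriptions of summary concentration tables from preclinical
#' niraparib/olaparib brain-penetration studies, shipped so the partition
#' arithmetic can be exercised on real printed values: `"gl261"` (orthotopic
#' glioblastoma mice, 2 h and 24 h), `"mouse_bm"` (brain-metastasis model,
#' BM and no-BM groups) and `"nhp"` (healthy rhesus macaques, per animal).
#'
#' @param study One of `"gl261"`, `"mouse_bm"`, `"nhp"`.
#' @return A tibble with `label`, `plasma` (ng/mL), `brain` (ng/g), `tumor`
#'   (ng/g, `NA` where not measured) and study-specific annotation columns.
#' @export
example_group_means <- function(study = c("gl261", "mouse_bm", "nhp")) {
  study <- match.arg(study)
  path <- system.file("extdata", paste0(study, "_group_means.csv"),
                      package = "msikp", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Render an 8-bit ion image from a concentration image
#'
#' Linear intensity mapping clipped to `[lob, upper]`: a pixel at the limit
#' of blank maps to 0, a pixel at the upper display bound (default 2000
#' ng/g, i.e. 2 ug/g) maps to 255, values above are clipped, and below-LOB
#' or off-tissue pixels render as background (0).
#'
#' @param conc A [quantify_image()] result or a numeric ng/g matrix.
#' @param lob Lower display bound in ng/g (defaults to the image LOD for a
#'   `concentration_image`).
#' @param upper Upper display bound in ng/g (default 2000).
#' @param file Optional PNG path; written as 8-bit grayscale.
#' @return Invisibly, the integer 0-255 matrix.
#' @export
render_ion_image <- function(conc, lob = NULL, upper = 2000, file = NULL) {
  m <- if (inherits(conc, "concentration_image")) conc$conc else conc
  if (!is.matrix(m) || !length(m)) {
    stop_msikp("nothing to render: empty image", "msikp_render_error")
  }
  if (is.null(lob)) {
    lob <- if (inherits(conc, "concentration_image")) conc$lod_conc else 0
  }
  if (upper <= lob) {
    stop_msikp("`upper` must exceed `lob`", "msikp_input_error")
  }
  v <- (m - lob) / (upper - lob) * 255
  v[!is.finite(v)] <- 0
  v[v < 0] <- 0
  v[v > 255] <- 255
  img <- matrix(as.integer(round(v)), nrow(m), ncol(m))
  if (!is.null(file)) {
    png::writePNG(img / 255, target = file)
  }
  invisible(img)
}
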
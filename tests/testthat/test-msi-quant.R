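test_that("ppm window arithmetic and exclusion behave as specified", {
  # 2-ppm total window around 500: [499.9995, 500.0005]
  pk <- list(data.frame(mz = 500.0010, intensity = 7),
             data.frame(mz = 500.0004, intensity = 3),
             NULL, data.frame(mz = numeric(0), intensity = numeric(0)))
  img <- extract_channel(pk, 500, window_ppm = 2, dim = c(2, 2))
  expect_equal(as.vector(img), c(0, 3, 0, 0))
  expect_error(
    extract_channel(list(data.frame(mz = c(2, 1), intensity = c(1, 1))),
                    500, 2, dim = c(1, 1)),
    class = "msikp_input_error")
})

test_that("extract_channel matches a brute-force per-peak scan", {
  set.seed(42)
  n <- 50
  pks <- lapply(seq_len(n), function(i) {
    m <- sort(runif(sample(0:8, 1), 499.999, 500.001))
    data.frame(mz = m, intensity = runif(length(m), 0, 10))
  })
  target <- 500
  w <- 2
  img <- extract_channel(pks, target, w, dim = c(5, 10))
  lower <- target * (1 - w / 2 * 1e-6)
  upper <- target * (1 + w / 2 * 1e-6)
  brute <- vapply(pks, function(pk) {
    s <- 0
    for (j in seq_along(pk$mz)) {
      if (pk$mz[j] >= lower && pk$mz[j] <= upper) s <- s + pk$intensity[j]
    }
    s
  }, numeric(1))
  expect_equal(as.vector(img), brute)
})

test_that("LOB/LOD estimation follows the blank-quantile closed form", {
  expect_equal(estimate_lob_lod(rep(0, 40), rep(0, 40), slope = 1)$lob, 0)
  expect_equal(estimate_lob_lod(rep(0, 40), rep(0, 40), slope = 1)$lod_conc, 0)
  expect_error(estimate_lob_lod(rnorm(10)), class = "msikp_estimation_error")
  set.seed(1)
  b <- rnorm(2e4, 50, 5)
  l <- estimate_lob_lod(b, numeric(0))
  expect_lt(abs(l$lob / (50 + qnorm(0.95) * 5) - 1), 0.01)
  # LOD: signal must clear LOB by z * sd(low)
  l2 <- estimate_lob_lod(rep(2, 40), c(1, 3), slope = 4, intercept = 1)
  expect_equal(l2$lod_conc,
               (2 + qnorm(0.95) * sqrt(2) - 1) / 4)
})

test_that("normalization decision: exact equality is no, strong shift is yes", {
  set.seed(3)
  blank <- rlnorm(200, 2, 0.4)
  expect_false(decide_normalization(blank, blank)$normalize)
  expect_true(decide_normalization(blank * 1e3, blank)$normalize)
  # degenerate zero-variance inputs use exact comparison of means
  expect_false(decide_normalization(rep(5, 10), rep(5, 10))$normalize)
  expect_true(decide_normalization(rep(50, 10), rep(5, 10))$normalize)
})

test_that("pixel normalization identities, floor accounting and spray-failure
           error", {
  a <- matrix(runif(20, 1, 5), 4, 5)
  ones <- matrix(1, 4, 5)
  expect_equal(unclass(normalize_pixels(a, ones, floor = 0.5))[, ],
               a, ignore_attr = TRUE)
  r <- normalize_pixels(a, a)
  expect_true(all(r == 1))
  expect_error(normalize_pixels(a, matrix(0, 4, 5)),
               class = "msikp_normalization_error")
  is_ch <- matrix(c(0, rep(2, 19)), 4, 5)
  r2 <- normalize_pixels(a, is_ch)
  expect_equal(attr(r2, "n_floor_substitutions"), 1L)
})

test_that("IS normalization cancels drift: ratio CV below raw CV in a
           uniform-truth region", {
  # suppression/drift variation dominating pixel noise is the regime the
  # shared-field cancellation addresses
  out <- generate_msi_dataset(
    fast_config(suppression_cv = 0.3, suppression_scale = 10,
                pixel_noise_cv = 0.02), 12)
  px <- roi_pixels(out$masks, "parenchyma")
  raw_cv <- sd(out$dataset$analyte[px]) / mean(out$dataset$analyte[px])
  ratio <- normalize_pixels(out$dataset$analyte, out$dataset$is)
  ratio_cv <- sd(ratio[px]) / mean(ratio[px])
  expect_lt(ratio_cv, raw_cv)
})

test_that("calibration fit recovers an exact line and validates inputs", {
  levels <- c(0.1, 0.2, 0.3, 0.5, 1, 5, 10, 25, 50, 75, 100)
  series <- structure(list(
    levels = levels,
    values = lapply(levels, function(l) rep(0.002 * l, 50)),
    blank_values = rep(0, 50),
    normalized = TRUE
  ), class = "calibration_series")
  fit <- fit_calibration(series)
  expect_equal(fit$slope, 0.002, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$weighting, "1/x")
  # decreasing response -> negative slope -> calibration failure
  bad <- series
  bad$values <- lapply(levels, function(l) rep(0.002 * (100 - l), 50))
  expect_error(fit_calibration(bad), class = "msikp_calibration_error")
})

test_that("the default mimetic model uses the 11 standard levels plus blank", {
  cfg <- study_config()
  expect_equal(cfg$calibration_levels,
               c(0.1, 0.2, 0.3, 0.5, 1, 5, 10, 25, 50, 75, 100))
  out <- generate_msi_dataset(fast_config(), 1)
  map <- out$masks$label_map
  expect_equal(sum(map$role == "core_blank"), 1L)
  expect_equal(sum(map$role == "core_level"), 11L)
})

test_that("calibration slope is recovered within 3% at 5% pixel noise", {
  cfg <- fast_config(pixel_noise_cv = 0.05, suppression_cv = 0,
                     spray_drift_amplitude = 0, baseline_intensity = 0)
  truth_slope <- cfg$response_analyte / (cfg$response_is * cfg$is_nominal_conc)
  slopes <- vapply(1:20, function(s) {
    out <- generate_msi_dataset(cfg, s)
    ratio <- normalize_pixels(out$dataset$analyte, out$dataset$is)
    fit_calibration(calibration_series(ratio, out$masks))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) / truth_slope - 1), 0.03)
})

test_that("back-calculation inverts the line and censors below the LOD", {
  fit <- structure(list(slope = 0.002, intercept = 0.1, r_squared = 1,
                        weighting = "1/x", normalized = FALSE,
                        per_pixel = FALSE, lob = 0.1, lod_conc = 50,
                        lod_overridden = FALSE, levels_used = 1:5,
                        alpha = 0.05),
                   class = "calibration_fit")
  img <- matrix(c(0.1, 1.0, 0.05), 1, 3)
  ci <- quantify_image(img, fit)
  # value = intercept -> conc 0 -> below LOD, substituted at LOD/2
  expect_equal(ci$conc[1, 1], 25)
  expect_equal(ci$censor[1, 1], "below_lod")
  # (1.0 - 0.1)/0.002 = 450 ug/g = 450000 ng/g
  expect_equal(ci$conc[1, 2], 450000)
  expect_equal(ci$censor[1, 2], "quantified")
  # negative raw conc clips to 0 then censors
  expect_equal(ci$conc[1, 3], 25)
  # channel-type mismatch is a usage error
  nimg <- img
  attr(nimg, "normalized") <- TRUE
  expect_error(quantify_image(nimg, fit), class = "msikp_usage_error")
})

test_that("raising the LOD never increases the number of quantified pixels", {
  out <- generate_msi_dataset(fast_config(), 4)
  ratio <- normalize_pixels(out$dataset$analyte, out$dataset$is)
  fit <- fit_calibration(calibration_series(ratio, out$masks))
  n_quant <- vapply(c(0, 50, 200, 1000, 5000), function(lod) {
    f <- fit
    f$lod_conc <- lod
    sum(quantify_image(ratio, f, out$masks)$censor == "quantified")
  }, numeric(1))
  expect_true(all(diff(n_quant) <= 0))
})

test_that("ROI summaries follow the stated censoring arithmetic", {
  ci <- tiny_conc_image(c(1, 2, 3, 100), lod = 0)
  s <- summarize_roi(ci, tiny_masks(4), "blob")
  expect_equal(s$mean, 26.5)
  expect_equal(s$median, 2.5)
  # uniform ROI
  su <- summarize_roi(tiny_conc_image(rep(7, 5)), tiny_masks(5), "blob")
  expect_equal(su$mean, 7)
  expect_equal(su$sd, 0)
  expect_equal(su$median, 7)
  # censoring policies: LOD 10 censors {1,2,3} at substitution 5
  ci2 <- tiny_conc_image(c(1, 2, 3, 100), lod = 10)
  m <- tiny_masks(4)
  expect_equal(summarize_roi(ci2, m, "blob")$mean, mean(c(5, 5, 5, 100)))
  expect_equal(summarize_roi(ci2, m, "blob", "exclude")$mean, 100)
  expect_equal(summarize_roi(ci2, m, "blob", "zero")$mean, 25)
  expect_equal(summarize_roi(ci2, m, "blob")$fraction_censored, 0.75)
  expect_error(summarize_roi(ci, m, "nothing"), class = "msikp_roi_error")
})

test_that("animal aggregation is an unweighted mean of section means", {
  s1 <- tibble::tibble(roi = "tissue", n_pixels = c(10L, 9000L),
                       mean = c(100, 300), sd = c(1, 1),
                       median = c(100, 300), fraction_censored = 0,
                       censor_policy = "substitute")
  agg <- aggregate_animal(s1)
  expect_equal(agg$mean, 200) # not pixel-count weighted
  s2 <- s1[rep(1, 12), ]
  expect_equal(aggregate_animal(s2)$sd, 0)
  s3 <- s1
  s3$roi <- c("tissue", "tumor")
  expect_error(aggregate_animal(s3), class = "msikp_usage_error")
})

test_that("whole-tissue summary equals the pixel-weighted combination of
           disjoint sub-region summaries", {
  out <- generate_msi_dataset(fast_config(), 8)
  q <- quantify_section(out$dataset, out$masks)
  s <- q$summaries
  sub <- s[s$roi %in% c("parenchyma", "ventricle", "tumor"), ]
  expect_equal(sum(sub$mean * sub$n_pixels) / sum(sub$n_pixels),
               s$mean[s$roi == "tissue"], tolerance = 1e-12)
})
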
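# Statistical layer: Welch's two-sample test on section concentrations and
# the nested mixed-effects model on log10-transformed ROI concentrations with
# estimated marginal means.

#' Welch's unpaired two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p-value, used to compare per-section concentrations
#' between treatment groups. Zero-variance degenerate inputs are handled by
#' an exact-equality convention instead of NaN propagation: equal constant
#' samples give `t = 0, p = 1`; distinct constant samples give `p = 0`.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return A list: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop_msikp("each sample needs at least 2 values", "msikp_input_error")
  }
  res <- tryCatch(t.test(x, y, var.equal = FALSE), error = function(e) NULL)
  if (is.null(res)) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, p_value = if (equal) 1 else 0,
                mean_x = mean(x), mean_y = mean(y)))
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Assemble section-level observations for the mixed model
#'
#' One row per ROI per section, with the response the study's transform
#' `log10(concentration [ng/g] + 0.001)` of the per-ROI median concentration.
#'
#' @param summaries Tibble with columns `animal_id`, `plane`, `roi`,
#'   `treatment`, optionally `tumor_group`, and `median` (ng/g).
#' @return A tibble with the added `log_conc` response column and
#'   factor-coded design columns.
#' @export
section_observations <- function(summaries) {
  needed <- c("animal_id", "plane", "roi", "treatment", "median")
  if (!all(needed %in% names(summaries))) {
    stop_msikp(sprintf("summaries must contain columns: %s",
                       paste(needed, collapse = ", ")),
               "msikp_input_error")
  }
  obs <- tibble::as_tibble(summaries)
  obs$log_conc <- log10(obs$median + 0.001)
  for (f in intersect(c("animal_id", "plane", "roi", "treatment",
                        "tumor_group"), names(obs))) {
    obs[[f]] <- factor(obs[[f]])
  }
  obs
}

#' Fit the nested mixed-effects model on regional concentrations
#'
#' Restricted-likelihood (REML) fit of `log10(conc + 0.001)` with random
#' intercepts for animal and for plane nested within animal, via
#' [lmerTest::lmer()] (Satterthwaite degrees of freedom for coefficient
#' tests). Two study designs are built in:
#'
#' * `"nhp"`: fixed effects treatment, region and their two-way interaction;
#' * `"mouse-bm"`: treatment, region, metastasis group and all two- and
#'   three-way interactions.
#'
#' Factors with fewer than two observed levels are dropped from the fixed
#' part (with a message), so single-treatment synthetic runs fit cleanly.
#' Singular fits are reported in the returned diagnostics, not hidden.
#'
#' @param observations A [section_observations()] tibble (needs `log_conc`,
#'   `animal_id`, `plane` and the design factors).
#' @param design `"mouse-bm"` or `"nhp"`, or `NULL` when `fixed` is given.
#' @param fixed Optional right-hand-side formula for the fixed effects,
#'   overriding `design`.
#' @return An object of class `msikp_mixed_fit`: the `lmerMod` fit (`model`),
#'   `fixed_effects` (coefficient table with Satterthwaite df and p),
#'   `variance_components`, `singular` flag and the formula used.
#' @export
fit_mixed_model <- function(observations, design = c("mouse-bm", "nhp"),
                            fixed = NULL) {
  obs <- observations
  if (!all(c("log_conc", "animal_id", "plane") %in% names(obs))) {
    stop_msikp("observations must carry log_conc, animal_id and plane",
               "msikp_input_error")
  }
  if (length(unique(obs$animal_id)) < 2) {
    stop_msikp("at least 2 animals are required", "msikp_input_error")
  }
  if (is.null(fixed)) {
    design <- match.arg(design)
    terms <- if (design == "nhp") {
      c("treatment", "roi")
    } else {
      c("treatment", "roi", "tumor_group")
    }
    terms <- terms[terms %in% names(obs)]
    terms <- terms[vapply(terms,
                          function(t) length(unique(obs[[t]])) >= 2,
                          logical(1))]
    if (!length(terms)) {
      stop_msikp("no fixed-effect factor has 2 or more levels",
                 "msikp_input_error")
    }
    rhs <- paste(terms, collapse = " * ")
  } else {
    rhs <- paste(deparse(fixed[[length(fixed)]]), collapse = " ")
  }
  form <- stats::as.formula(paste(
    "log_conc ~", rhs, "+ (1 | animal_id) + (1 | animal_id:plane)"))
  model <- lmerTest::lmer(form, data = obs, REML = TRUE)
  singular <- lme4::isSingular(model)
  if (singular) {
    message("mixed-model fit is singular (a variance component is zero)")
  }
  co <- as.data.frame(summary(model)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p_value")
  co <- tibble::as_tibble(co, rownames = "term")
  vc <- as.data.frame(lme4::VarCorr(model))
  variance_components <- tibble::tibble(
    component = vc$grp, variance = vc$vcov, sd = vc$sdcor
  )
  structure(list(model = model, formula = form, fixed_effects = co,
                 variance_components = variance_components,
                 singular = singular),
            class = "msikp_mixed_fit")
}

#' @export
print.msikp_mixed_fit <- function(x, ...) {
  cat("<msikp_mixed_fit>", deparse(x$formula), "\n")
  cat(sprintf("  singular: %s\n", x$singular))
  print(x$fixed_effects)
  invisible(x)
}

#' Estimated marginal means from the mixed-model fit
#'
#' Model-based cell means per factor combination, averaged over the other
#' design factors with equal weights, with confidence intervals from the
#' fit's covariance (via the emmeans package). EMMs are computed on the
#' `log10(conc + 0.001)` scale; a back-transformed column
#' `response_ng_g = 10^emmean - 0.001` is reported alongside. The
#' back-transform estimates the median, not the mean, of the concentration
#' distribution (lognormal retransformation bias is not corrected).
#'
#' @param fit A [fit_mixed_model()] result.
#' @param specs Factor name(s) to condition on, e.g. `"treatment"` or
#'   `c("treatment", "roi")`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with the factor columns, `emmean`, `se`, `df`,
#'   `lower_cl`, `upper_cl` (transformed scale) and `response_ng_g`.
#' @export
estimated_marginal_means <- function(fit, specs, level = 0.95) {
  stopifnot(inherits(fit, "msikp_mixed_fit"))
  em <- emmeans::emmeans(fit$model, specs = specs, level = level,
                         lmer.df = "satterthwaite")
  tab <- as.data.frame(em)
  k <- length(specs)
  names(tab)[(k + 1):ncol(tab)] <-
    c("emmean", "se", "df", "lower_cl", "upper_cl")
  tab$response_ng_g <- 10^tab$emmean - 0.001
  tibble::as_tibble(tab)
}
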
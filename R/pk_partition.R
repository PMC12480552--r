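# Partition-coefficient arithmetic: homogenate back-calculation, equilibrium-
# dialysis dilution correction of unbound fractions, Kp brain / Kp,uu brain /
# Kp tumor, and group aggregation with explicit BQL policies.

#' Convert a homogenate concentration to a tissue concentration
#'
#' Brain samples are homogenized after adding buffer at `dilution:1`
#' volume:weight (1:4 w:v, i.e. a 5x dilution, by default), so
#' `tissue (ng/g) = homogenate (ng/mL) * (1 + dilution)` under the standard
#' density assumption 1 g tissue ~ 1 mL.
#'
#' @param conc_homog Homogenate concentration in ng/mL (non-negative).
#' @param dilution_wv Added-volume:tissue-weight ratio (default 4).
#' @return Tissue concentration in ng/g.
#' @export
homogenate_to_tissue <- function(conc_homog, dilution_wv = 4) {
  if (any(conc_homog < 0, na.rm = TRUE) || dilution_wv < 0) {
    stop_msikp("concentrations and dilution must be non-negative",
               "msikp_input_error")
  }
  conc_homog * (1 + dilution_wv)
}

#' Correct a diluted-matrix unbound fraction to the undiluted matrix
#'
#' Equilibrium dialysis on diluted tissue (brain is typically diluted 1:4,
#' a 5x dilution) measures an apparent unbound fraction that overstates the
#' undiluted value. The standard mass-balance correction is
#' `fu = (1/D) / (1/fu_measured - 1 + 1/D)`.
#'
#' @param fu_measured Apparent unbound fraction in the diluted matrix,
#'   in (0, 1].
#' @param D Dilution factor (>= 1; `D = 1` returns `fu_measured` unchanged).
#' @return The undiluted-matrix unbound fraction, in (0, 1].
#' @export
correct_fu_dilution <- function(fu_measured, D = 1) {
  if (any(!is.finite(fu_measured)) || any(fu_measured <= 0) ||
      any(fu_measured > 1)) {
    stop_msikp("`fu_measured` must lie in (0, 1]", "msikp_input_error")
  }
  if (any(D < 1)) {
    stop_msikp("`D` must be >= 1", "msikp_input_error")
  }
  (1 / D) / (1 / fu_measured - 1 + 1 / D)
}

#' Brain-to-plasma partition coefficient (total drug)
#'
#' `Kp_brain = C_ss_brain / C_ss_plasma`, the ratio of total steady-state
#' brain tissue concentration (ng/g) to total plasma concentration (ng/mL).
#' Values are returned unrounded; report tables round to 3 decimals with
#' [round_report()].
#'
#' @param c_brain Brain tissue concentration, ng/g (>= 0).
#' @param c_plasma Plasma concentration, ng/mL (> 0).
#' @return The unitless partition coefficient.
#' @export
kp_brain <- function(c_brain, c_plasma) {
  if (any(c_plasma <= 0, na.rm = TRUE)) {
    stop_msikp("`c_plasma` must be positive (BQL plasma gives status NC)",
               "msikp_input_error")
  }
  if (any(c_brain < 0, na.rm = TRUE)) {
    stop_msikp("`c_brain` must be non-negative", "msikp_input_error")
  }
  c_brain / c_plasma
}

#' Unbound brain-to-plasma partition coefficient
#'
#' `Kp_uu_brain = Kp_brain * (fu_brain / fu_plasma)`, equivalently the ratio
#' of unbound concentrations `C_u_brain / C_u_plasma`. Reflects the net
#' balance of drug influx and efflux across the blood-brain barrier: values
#' near 1 indicate passive equilibration, values well below 1 net efflux.
#'
#' @param kp Total partition coefficient from [kp_brain()].
#' @param fu_brain,fu_plasma Unbound fractions in (0, 1].
#' @return The unbound partition coefficient.
#' @export
kp_uu_brain <- function(kp, fu_brain, fu_plasma) {
  if (any(fu_brain <= 0) || any(fu_brain > 1) ||
      any(fu_plasma <= 0) || any(fu_plasma > 1)) {
    stop_msikp("unbound fractions must lie in (0, 1]", "msikp_input_error")
  }
  kp * (fu_brain / fu_plasma)
}

#' Tumor-to-plasma partition coefficient (total drug)
#'
#' Ratio of the mean tumor tissue concentration (typically the tumor-ROI
#' mean from MSI, ng/g) to the terminal plasma concentration (ng/mL).
#'
#' @param c_tumor Tumor concentration, ng/g (>= 0).
#' @param c_plasma Plasma concentration, ng/mL (> 0).
#' @return The unitless partition coefficient.
#' @export
kp_tumor <- function(c_tumor, c_plasma) {
  if (any(c_plasma <= 0, na.rm = TRUE)) {
    stop_msikp("`c_plasma` must be positive", "msikp_input_error")
  }
  if (any(c_tumor < 0, na.rm = TRUE)) {
    stop_msikp("`c_tumor` must be non-negative", "msikp_input_error")
  }
  c_tumor / c_plasma
}

#' Report rounding for partition coefficients
#'
#' Half-away-from-zero rounding to 3 decimals, the convention used in the
#' report tables.
#'
#' @param x Numeric vector.
#' @param digits Decimals (default 3).
#' @return Rounded vector.
#' @export
round_report <- function(x, digits = 3) {
  round_half_away(x, digits)
}

#' Group-level partition summary with explicit aggregation and BQL policy
#'
#' Computes Kp brain (and Kp tumor where tumor concentrations exist) for a
#' group of animals under one of two first-class aggregation conventions:
#'
#' * `"mean-of-ratios"`: the per-animal ratio is computed first and averaged,
#'   with an SD across animals (the convention behind parenthesized group
#'   SDs);
#' * `"ratio-of-means"`: a single ratio of the group mean concentrations, no
#'   SD (the convention behind single unparenthesized group ratios).
#'
#' An animal contributes to a ratio only if both its numerator and
#' denominator matrices are at or above the LLOQ; if fewer than
#' `min_detectable_fraction` of the group's animals are evaluable the result
#' is `NC` (not calculated) with the detectability fraction reported.
#'
#' @param records Bioanalysis tibble as from [generate_bioanalysis_table()]
#'   (columns `plasma_conc`, `plasma_bql`, `brain_tissue_conc`, `brain_bql`,
#'   optionally `tumor_conc`, `tumor_bql`).
#' @param fu_brain,fu_plasma Unbound fractions for the Kp,uu step; `NA` skips
#'   it.
#' @param method Aggregation convention.
#' @param min_detectable_fraction Minimum evaluable-animal fraction below
#'   which the ratio is NC (default 0.5).
#' @return A one-row tibble with the group size, evaluable counts, Kp values
#'   (and SDs under mean-of-ratios), Kp,uu, Kp tumor, the aggregation label
#'   and a `status` column (`"computed"` or `"NC: <reason>"`).
#' @export
group_partition_summary <- function(records,
                                    fu_brain = NA_real_,
                                    fu_plasma = NA_real_,
                                    method = c("mean-of-ratios",
                                               "ratio-of-means"),
                                    min_detectable_fraction = 0.5) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  n <- nrow(records)

  ok_brain <- !records$plasma_bql & !records$brain_bql
  frac_brain <- mean(ok_brain)
  has_tumor <- "tumor_conc" %in% names(records) &&
    any(is.finite(records$tumor_conc))
  if (has_tumor) {
    ok_tumor <- !records$plasma_bql & is.finite(records$tumor_conc) &
      !(records$tumor_bql %in% TRUE)
    frac_tumor <- mean(ok_tumor)
  }

  ratio_stats <- function(num, den, ok, frac) {
    if (!any(ok) || frac < min_detectable_fraction) {
      return(list(kp = NA_real_, sd = NA_real_,
                  status = sprintf("NC: %d/%d animals evaluable",
                                   sum(ok), n)))
    }
    if (method == "mean-of-ratios") {
      r <- num[ok] / den[ok]
      list(kp = mean(r), sd = if (sum(ok) > 1) sd(r) else NA_real_,
           status = "computed")
    } else {
      list(kp = mean(num[ok]) / mean(den[ok]), sd = NA_real_,
           status = "computed")
    }
  }

  bs <- ratio_stats(records$brain_tissue_conc, records$plasma_conc,
                    ok_brain, frac_brain)
  kp_uu <- if (is.finite(fu_brain) && is.finite(fu_plasma) &&
               is.finite(bs$kp)) {
    kp_uu_brain(bs$kp, fu_brain, fu_plasma)
  } else {
    NA_real_
  }
  if (has_tumor) {
    ts <- ratio_stats(records$tumor_conc, records$plasma_conc,
                      ok_tumor, frac_tumor)
  } else {
    ts <- list(kp = NA_real_, sd = NA_real_, status = "NC: no tumor data")
    frac_tumor <- NA_real_
  }

  tibble::tibble(
    n_animals = n,
    n_evaluable_brain = sum(ok_brain),
    detectable_fraction_brain = frac_brain,
    kp_brain = bs$kp, kp_brain_sd = bs$sd,
    kp_uu_brain = kp_uu,
    detectable_fraction_tumor = frac_tumor,
    kp_tumor = ts$kp, kp_tumor_sd = ts$sd,
    aggregation = method,
    status = if (bs$status == "computed") "computed" else bs$status,
    status_tumor = ts$status
  )
}
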
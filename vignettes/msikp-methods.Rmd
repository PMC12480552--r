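---
title: "Methods: quantitative MSI, partition coefficients, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative MSI, partition coefficients, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msikp)
```

# Scope

`msikp` quantifies small-molecule drug distribution in brain tissue from
two-channel MALDI MSI data (analyte + deuterated internal standard), converts
regional and bulk concentrations into blood–brain-barrier partition
coefficients, and provides the statistical layer used to compare treatments
and regions. Because real MSI studies rarely ship raw data, the package
includes a first-class synthetic study generator whose statistical structure
matches what the analysis assumes; every stage of the pipeline is tested
against its ground truth.

# The quantification model

## Signal model and calibration

Each pixel's analyte intensity is modeled as proportional to the local tissue
concentration, scaled by a spatially varying multiplicative ion-suppression
factor and pixel noise; the IS channel sees the same suppression (the IS is
sprayed uniformly with the matrix) plus a low-frequency spray-drift gradient.
The analyte/IS ratio therefore cancels suppression pixel-by-pixel, leaving
only drift and noise.

Calibration uses a mimetic tissue model: homogenate cores spiked at 0.1, 0.2,
0.3, 0.5, 1, 5, 10, 25, 50, 75 and 100 µg/g plus a blank, sectioned on the
same slide. `fit_calibration()` regresses the mean core response on nominal
level by weighted least squares. The default weighting is 1/x, the
bioanalytical convention for ranges spanning three orders of magnitude
(unweighted least squares would let the 100 µg/g core dominate the fit);
ordinary least squares is selectable. Core *means* enter the regression by
default — the per-pixel alternative is available (`per_pixel = TRUE`) but
gives the same line under the 1/x weighting while being dominated by the
pixel counts of individual cores. Fits with non-positive slope or R² below
0.90 raise a calibration-failure error rather than silently back-calculating
nonsense.

## Limits of blank and detection

`estimate_lob_lod()` uses the classical parametric definitions: LOB is the
mean blank-core signal plus z(1−α)·SD (z = 1.645 at the default α = 0.05);
LOD is the concentration whose expected signal clears the LOB by z·SD of the
lowest calibration level, obtained by inverting the standard curve. At least
30 blank pixels are required. A configuration override can pin the LOD to an
externally validated value (e.g. one established on a separate instrument
run), which is then honored verbatim in censoring.

## The conditional normalization rule

Pixel-level IS normalization is applied **only if** the whole-tissue ROI
signal is significantly above the blank-core ROI. Normalizing a section that
contains no real analyte signal divides noise by noise and manufactures
artifactual spatial structure; the conditional rule avoids this. The
significance criterion is not uniquely determined by the workflow it comes
from, so the package makes a concrete, config-exposed choice: a one-sided
Welch test on log10(intensity + 1) at α = 0.05, additionally requiring the
tissue mean to exceed the blank mean. Welch was chosen for consistency with
the package's group-comparison layer; the log transform stabilizes the
right-skewed intensity distributions; the +1 offset handles empty pixels.
Zero-variance degenerate inputs fall back to exact comparison of means.
Under the null the decision triggers at about the nominal α — this is
checked by simulation in the test suite.

## Back-calculation, censoring, and aggregation

`quantify_image()` inverts the line per pixel, clips negative concentrations
to zero, and flags pixels below the LOD. Censored pixels carry LOD/2 — the
common bioanalytical substitution — and every ROI summary reports its
censored fraction, so the convention is visible, not hidden; exclusion and
zero-substitution are selectable alternatives. ROI statistics (mean, SD,
median, pixel count) are computed by `summarize_roi()`; the median is what
feeds the mixed model downstream. Animal-level aggregation
(`aggregate_animal()`) is the unweighted mean of section means — each
section counts once regardless of pixel count, matching the reporting
convention of section-replicate MSI studies.

The IS floor in ratio images is 1% of the median nonzero IS intensity:
spray gaps would otherwise produce division blow-ups. Floor substitutions
are counted on the returned image.

The ppm window for channel extraction is interpreted as a *total* width
(a "2-ppm export" means ±1 ppm); this is config-exposed since vendor
conventions differ.

# Partition coefficients

`kp_brain()` and `kp_tumor()` are plain concentration ratios, kept unrounded
internally; report tables round half-away-from-zero to 3 decimals
(`round_report()`). `kp_uu_brain()` multiplies by the unbound-fraction ratio
F_u,brain/F_u,plasma. Brain F_u is measured by rapid equilibrium dialysis on
diluted homogenate (1:4, i.e. 5×); `correct_fu_dilution()` applies the
standard mass-balance correction

    fu_undiluted = (1/D) / (1/fu_measured − 1 + 1/D),

which follows from the bound:free ratio scaling linearly with matrix protein
concentration. The correction is monotone in `fu_measured`, maps (0,1] onto
(0,1] for every D ≥ 1, and is the identity at D = 1 — all property-tested.

Homogenate concentrations convert to tissue concentrations by the factor
(1 + dilution) under the density assumption 1 g tissue ≈ 1 mL, stated in all
reports.

## Aggregation conventions and BQL policy

Group summaries support two first-class conventions because both appear in
practice: **mean-of-ratios** (per-animal K_p averaged, with SD) and
**ratio-of-means** (single ratio of group means, no SD). They coincide at
zero inter-animal variance; with independent lognormal numerator and
denominator the mean-of-ratios is systematically larger (a Jensen-type gap,
verified by simulation in the tests). Every report carries an aggregation
column. An animal contributes to a ratio only when both matrices are at or
above the LLOQ; groups with under 50% evaluable animals return NC with the
detectability fraction, mirroring how sparse-detection groups are reported
in practice. Censored bioanalysis entries carry the LLOQ itself, flagged,
never an imputed number.

# Statistical layer

`welch_t_test()` wraps the unequal-variance t-test (two-tailed,
Welch–Satterthwaite df) with an exact-equality convention for zero-variance
inputs (equal constants → p = 1) instead of NaN propagation.

`fit_mixed_model()` fits `log10(concentration [ng/g] + 0.001)` by REML with
nested random intercepts for animal and plane-within-animal, via
`lmerTest::lmer` (Satterthwaite df for coefficient tests). The +0.001 offset
is fixed, not configurable, to keep reports comparable across runs. Two
design presets exist: `"nhp"` (treatment × region) and `"mouse-bm"`
(treatment × region × metastasis group with all interactions); factors with
fewer than two observed levels are dropped with a message so single-arm
synthetic runs fit cleanly. Singular fits are flagged in the returned
diagnostics, never silently accepted. Note the nested plane intercept needs
replication within each animal × plane cell (multiple ROIs or sections per
plane); with one observation per cell it is unidentifiable and `lmer`
refuses the fit.

`estimated_marginal_means()` (via emmeans) averages model cell means with
equal weights. EMMs are computed on the transformed scale; the
back-transformed column `10^emmean − 0.001` estimates the *median*
concentration — lognormal retransformation bias is deliberately not
corrected, and the column is documented as such.

How below-LOD sections enter the model follows the upstream censoring policy
(LOD/2 by default) and is recorded in the run manifest, since exclusion
versus substitution is a genuine free choice here.

# The synthetic study generator

## What it emulates

The defaults describe a mouse brain-metastasis study arm: groups of 4 (BM)
and 3 (no-BM) animals, 5 section planes per animal, terminal plasma around
2535/3847 ng/mL and bulk brain around 543/658 ng/g (BM/no-BM) with
geometric SD 1.2 inter-animal lognormal variability, tumor truth 1700 ng/g,
ventricle truth 1860 ng/g, and a whole-section mean of 487 ng/g on a
200 × 200 grid at 75 µm. The parenchyma level is *solved* from the
whole-section target and the region geometry (about 403 ng/g at the default
geometry), so the section-level truth is internally consistent by
construction. The unbound fractions default to 0.07 (brain) and 0.50
(plasma) — a synthetic choice giving an F_u ratio of 0.14, in the range
implied by published K_p,uu/K_p pairs for a brain-penetrant PARP inhibitor.

Noise structure: a shared multiplicative lognormal suppression field
(default CV 0.20) built by bilinear interpolation of coarse white noise
(correlation scale 40 px ≈ 3 mm — the spatial autocorrelation of suppression
in real tissue is not established, so this scale is a free parameter, not a
claim about data); a linear IS-only spray-drift gradient along x (the
sprayer pass direction, default amplitude ±15%); independent per-channel
lognormal pixel noise (CV 0.10); and an additive analyte-channel baseline
(mean 10 counts) that gives the blank core a realistic nonzero LOB.

The calibration array uses 12 cores (11 levels + blank) of 20 px diameter in
two rows of six. A 40 px (3 mm) core at the real-array scale cannot fit
twelve-across on a 200 px grid alongside the tissue section, so the default
trades core diameter for a desk-sized grid; all geometry is configurable.

One master seed expands into named substreams (suppression, per-channel
noise, baseline, per-section, per-group bioanalysis), so adding a component
never perturbs the draws of another, and identical (config, seed) pairs are
bit-for-bit reproducible — including the written report CSVs.

## What it does not emulate

No raw profile spectra, isotope patterns or peak picking (channels are
already peak-integrated intensities); no tumor-growth kinetics or histology;
no registration error between masks and images (masks are exact); no
animal-to-animal variation in the *MSI* truth map (section truth is fixed at
the configured region levels; inter-animal variability lives in the
bioanalysis tables). Passing recovery tests therefore demonstrates that the
pipeline arithmetic and the normalization/calibration logic are correct
under the assumed noise structure — not that any particular real tissue
satisfies that structure.

# Numerical and design choices

- Images are base-R numeric matrices indexed `[row, column]`, 1-based,
  column-major — the native R convention, used consistently by masks and
  channels.
- Noise-free round trips recover truth to ~1e-15 relative; the test suite
  asserts 0.1%.
- The ion-image display convention maps [LOB, 2 µg/g] linearly onto 0–255,
  clipping above and rendering below-LOB pixels as background.
- Tie-breaks and degenerate inputs: zero-variance Welch inputs use exact
  equality; an all-zero IS channel is a hard error (spray failure), not a
  silent fallback; empty ROIs and grid mismatches raise classed errors.
- Problem sizes in the tests and acceptance script — 20 seeded sections for
  recovery checks, 1,000 trials for the normalization null rate, 10,000
  draws for Welch type-I error, 200 replicates of the 4 + 3 animal × 5 plane
  mixed-model design, 10 end-to-end pipeline runs — were chosen to bound
  Monte-Carlo error comfortably below the tolerances being asserted.

# Known limitations

- The conditional-normalization significance rule is a package choice among
  reasonable alternatives; its α and test are exposed, and results should be
  read with that in mind.
- LOD/2 substitution biases ROI means upward in heavily censored regions;
  the censored fraction is always reported so users can switch policy.
- Group ratios computed from rounded published summary concentrations will
  not always reproduce published per-animal ratio means (those were computed
  from unrounded source data); the package reproduces exactly the arithmetic
  that closes on printed values and reports the rest unrounded.
- The mixed-model layer assumes the ROI medians are approximately lognormal;
  gross departures (e.g. heavy censoring) propagate into the EMMs.
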
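---
title: "Normative single-subject tract analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative single-subject tract analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixelnorm)
```

This vignette is the package's own account of the statistics it
implements: the processing model, the parameters that matter and their
defaults, what the synthetic generator does and does not emulate, the
numerical choices, and the places where the design was genuinely open.

## The processing model

The unit of analysis is the *fixel* — one fibre population within one
voxel of a shared template — carrying a fibre density and cross-section
(FDC) value per subject. FDC is unitless and non-negative; reduced FDC is
the abnormality of interest. The pipeline runs six stages:

1. **Tract reduction.** Mean FDC over each tract's fixel mask. Masks are
   binarized streamline-density images (`mask_from_density()`, default
   threshold: density ≥ 1, i.e. at least one streamline). A missing value
   inside a mask is an error, never silently dropped — exclusion would
   change the estimand.
2. **Scanner harmonization.** Parametric empirical-Bayes ComBat, written
   in full here (`fit_combat()`/`apply_combat()`). Feature-wise
   standardization uses a least-squares fit of per-batch means plus
   optional covariates, with variance pooled across fit subjects
   (divisor *n*); per-batch location (`γ*`) and scale (`δ*`) effects are
   shrunk toward method-of-moments hyperpriors (normal on location,
   inverse-gamma on scale) by iterated conditional updates.
3. **Normality screening.** Shapiro–Wilk per tract across controls,
   advisory only: the transform in stage 4 is applied regardless, and the
   report documents how non-Gaussian the raw distributions were.
4. **Inverse normal transformation.** Blom-type rank-based INT,
   `Φ⁻¹((r − c)/(n − 2c + 1))` with midranks for ties and `c = 3/8`.
5. **Normative model.** Control mean `μ` and sample SD `σ` (divisor
   `n − 1`) per feature; zero-variance features are excluded with a
   recorded reason rather than producing infinite scores.
6. **Scoring.** `z = (x − μ)/σ`; abnormal where `z ≤ −1.96`. Positive
   deviations are reported but never flagged: the target pathology is FDC
   loss. The most-affected tract attains the minimum z (ties broken by
   feature order). The laterality index is
   `LI = (L_sum − R_sum)/(L_sum + R_sum)` over hemispheric Z-sums.

The same machinery runs per fixel (`fixel_stack()`, `fixel_zmap()`) to
produce whole-template Z-maps and −1.96-threshold masks. By default the
fixel-level route scores raw FDC without ComBat or INT: per-fixel
empirical-Bayes batch models and rank transforms at tens of thousands of
features are a different statistical regime, and the tract-level model is
where the harmonization design was validated. Per-fixel harmonization can
still be performed explicitly by building a fixel stack and passing it
through the same functions.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| mask density threshold | 1 | streamlines | at least one streamline; reproducible without tuning |
| ComBat `fit_on` | `"controls"` | – | patient pathology must not contaminate batch estimates; patients are adjusted with their batch's parameters at apply time (`"all"` mirrors a plain combined-table call) |
| ComBat covariates | none | – | the metadata records age/sex, but no covariate is assumed; `covariates = c("age", "sex")` preserves their effects through harmonization |
| EB convergence | `1e-6`, ≤ 500 iter | relative change | tighter than the common reference implementation's `1e-4`; the fixed point is contracted far below both, so results agree to ~1e-7 relative |
| INT offset `c` | 3/8 | – | the Blom constant, the default of the standard rank-normalization packages |
| INT `scope` | `"joint"` | – | the most literal reading of a column-wise transform of the combined table; `"controls_only"` + pseudo-midrank patient extension is the statistically safer alternative and what the leave-one-out calibration uses — the mode is recorded on the output |
| z threshold | −1.96 | SD | the two-sided 5% normal quantile, matching the display convention (dotted ring) |
| LI midline handling | exclude | – | the corpus callosum belongs to neither hemisphere; it is displayed on both spider layers but kept out of the sums (configurable) |

The patient extension of a controls-only INT mapping assigns the value
the pseudo-midrank `r* = #(controls < x) + 0.5·#(controls = x) + 0.5`, so
it is monotone, agrees with the control transform on control values, and
saturates one rank step beyond the control extremes
(`Φ⁻¹(0.125/90.25) ≈ −2.99` for a value below all of 90 controls). That
saturation is a deliberate bound: a single subject's evidence cannot rank
lower than "below everyone we have seen".

## The synthetic generator

`simulate_cohort()` draws, for subject *s* in batch *b* at fixel *f*:

```
x = mu0_f + age_slope * age_s + u_s + e
observed = mu0_f + shift_b + scale_b * (x - mu0_f),  truncated at 0
```

with per-fixel baselines `mu0_f` lognormal around `mu0` (FDC is
non-negative), a shared subject effect `u_s ~ N(0, (cv·mu0)²)` and
independent fixel noise `e`. Defaults emulate the normative study design
this package targets: 90 controls split across two scanners,
`mu0 = 0.5`, between-subject CV 10%, additive/multiplicative site
effects. This is exactly the location–scale structure ComBat assumes, so
harmonization is testable by construction; lesions
(`implant_lesion()`) multiply an extent-fraction of a tract's fixels by
`1 − reduction`.

What the generator does **not** emulate: spatial correlation between
neighbouring fixels (real data are connectivity-smoothed), orientation
dispersion effects, non-Gaussian site effects, or any dependence of FDC
variance on tract anatomy. Passing tests therefore demonstrate that the
*statistical machinery* is correct under its stated model, not that real
scanner effects are fully removed from real data.

Two measured consequences of the generative model are worth stating
plainly. First, with 90 controls the leave-one-out rank pipeline flags
`|z| > 1.96` at a rate of ~6.7% rather than 5.0%: with `n = 89` reference
values the extreme Blom scores exceed 1.96/σ̂ for exactly the three
lowest and three highest ranks, and 6/90 ≈ 0.067. This is a property of
rank-based scoring at this cohort size, not a bug. Second, a 25% tract
FDC reduction against a 10% between-subject CV yields a lesioned-tract Z
of roughly `N(−2.4, 0.75)` — the patient's own (still 0.75·CV) biological
variability propagates into the score — so the −1.96 flag has ~80–93%
power per cohort even though the lesioned tract is ranked most affected
in ≈99% of patients. Effect-size ranking is more robust than hard
thresholding at this lesion magnitude.

## Numerical choices and degenerate inputs

* Raster payloads are written 32-bit little-endian float by default
  (64-bit available when exact doubles matter); the index image is 32-bit
  unsigned. Offsets and voxel coordinates are 0-based; the
  voxel-to-scanner affine is carried opaquely and never interpreted.
  Unrecognized header keys round-trip verbatim and in order.
* `validate_template()` reports violations (count/direction mismatch,
  overlapping or out-of-range fixel ranges, non-unit directions at
  1e-4) and never raises; readers raise on an invalid template.
* A single batch yields a warned identity harmonization model rather than
  an error, so single-site studies flow through the same pipeline.
* Constant features are excluded from the normative model with a reason;
  requesting them in a report yields `NA` scores, and fixel Z-maps carry
  `NA` (NaN on disk) at excluded fixels.
* The EB update stops on relative change `< 1e-6` in both `γ*` and `δ*`;
  ties in the most-affected ranking break by feature order; `LI` errors
  when `L_sum + R_sum = 0` (undefined) and its magnitude may exceed 1
  when the hemispheric sums have opposite signs, in which case the sign
  is not interpretable as a lateralization.
* All generators consume an explicit seed and restore the caller's RNG
  state; identical seeds give byte-identical cohorts, and pipeline reruns
  with an identical configuration are numerically identical (provenance
  sidecars deliberately omit timestamps).

## Problem sizes in the test suite

The suite and the acceptance script size their simulations to what the
statistics need rather than to imaging scale: templates of 6³–12³ voxels
(a few hundred to ~1,000 fixels), 23 tracts, 90 controls, 100 seeds for
calibration-style rates and 100 simulated patients for detection rates.
All rates are recomputed from scratch at run time; none are stored.

## Known limitations

* Parametric EB priors only; no non-parametric ComBat, no longitudinal or
  GAM variants, and no per-fixel spatial priors.
* Harmonization is not exactly idempotent: EB shrinkage leaves
  per-feature residuals that a second fit shrinks again, changing values
  at the few-percent-of-σ level. The suite asserts the contraction
  property rather than exact idempotence.
* No multiple-comparison correction anywhere, by design: the intended use
  is effect-size screening of a single patient, where hard significance
  thresholds discard clinically relevant gradation.
* The spider display clamps `z > 0` to the outer ring and `z < −4`
  inward with a marker; it is a reading aid, not a quantitative plot —
  the CSV/JSON reports are the quantitative output.
* No tractography, bundle segmentation, registration or smoothing:
  fixel-space inputs are assumed prepared by the standard FBA tooling.
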
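---
title: "Quantifying glymphatic CSF-ISF exchange: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glymphatic CSF-ISF exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphkit)
```

## The scientific problem

The glymphatic system exchanges para-arterial cerebrospinal fluid (CSF)
with interstitial fluid (ISF) through astrocytic aquaporin-4 (AQP4) water
channels, clearing interstitial solutes — including tau — out of the brain.
Its function can be probed in rodents three ways, and this package
implements the quantitative analysis for all three:

1. **Dynamic contrast-enhanced MRI**: a gadolinium tracer infused into the
   cisterna magna enters the parenchyma; regional T1-weighted signal
   enhancement over ~3 h measures CSF-ISF exchange.
2. **Immunofluorescence of AQP4**: the degree to which AQP4 is polarized
   to perivascular astrocytic endfeet, and how much of each vessel is
   covered by AQP4-positive endfeet.
3. **Clearance assays**: ELISA quantification of tau in sampled CSF after
   parenchymal injection, supported by blood-contamination checks, qPCR
   expression and infusion arithmetic.

Because raw animal data for such studies are rarely deposited, every
estimator here is validated against a synthetic-data layer that generates
inputs with known ground truth.

## Inflow kinetics

Regional enhancement, expressed as percent change from the pre-infusion
baseline, is described by a logistic ("sigmoidal") curve

$$y(t) = \frac{I_{max}}{1 + e^{(T_{50} - t)/s}}$$

with three parameters: the plateau enhancement $I_{max}$ (%), the time to
half maximum $T_{50}$ (min), and the rise time-scale $s$ (min). The curve
passes through $I_{max}/2$ at $T_{50}$ exactly, and is symmetric about that
point. A single-number summary of regional tracer ingress, the
*penetration efficiency*, is the ratio $I_{max}/T_{50}$ (%/min): regions
that fill high and fast score high.

```{r}
f <- fit_sigmoid(simulate_roi_series(sigmoid_params(60.17, 39.66, 10),
                                     seq(12, 192, 12), noise_sd = 1,
                                     n_subjects = 5, seed = 1))
f
penetration_efficiency(f)
```

Fitting choices:

* **Estimator**: Levenberg–Marquardt least squares with a data-driven
  start ($I_{max}\leftarrow\max y$; $T_{50}\leftarrow$ first half-maximum
  crossing; $s\leftarrow$ a quarter of the time range) plus five jittered
  restarts under a fixed seed, keeping the lowest residual sum of squares.
* **Confidence intervals**: asymptotic, from the residual variance and the
  local curvature of the model, with $n-3$ degrees of freedom — the
  convention of standard curve-fitting software. The penetration-efficiency
  CI is propagated from the fit covariance by the first-order delta method,
  since the ratio's sampling distribution is not reported anywhere to
  compare against.
* **Pooling**: group curves are fitted to the pooled
  animals-by-frames point cloud; per-animal fits remain available by
  passing a single animal's series.
* **Baseline frames**: the model describes post-infusion inflow, so
  non-positive times (pre-infusion baselines, which are structurally zero)
  are excluded by default; `include_baseline = TRUE` restores them.
* **Slope units**: the slope is housed as the exponential time-scale in
  minutes. Published parameter tables for this assay report $I_{max}$ and
  $T_{50}$ but no slope, so the bundled reference table
  (`reference_inflow_fits()`) carries a demonstration slope of 10 min
  (12 min for the rTg4510 caudal cortex) for simulation use.

Two fitted groups are compared by the extra-sum-of-squares F test (one
shared curve versus separate curves), plus per-parameter z comparisons
from the asymptotic standard errors with the direction of each effect.

## DCE-MRI preprocessing

The conformant stage order is **register → bias-correct → smooth →
difference/extract**; `check_pipeline_order()` flags deviations.

* **Registration** (`register_series`): motion of an anaesthetized mouse
  head at 0.1 mm resolution is dominantly translational, so each frame's
  displacement relative to the average baseline is estimated as a pure
  translation: both images are lightly smoothed, the residual is
  linearized in the shift (Gauss–Newton), and the top 20 % of absolute
  residuals is trimmed each iteration so genuine tracer enhancement — a
  signal change, not motion — cannot bias the estimate. Full 6-DOF rigid
  registration is an extension hook, not implemented.
* **Bias correction** (`bias_correct`): the intensity non-uniformity field
  is the exponential of a second-order 3D polynomial fitted to the log of
  the average baseline, normalized to unit mean, and divided out of every
  frame. Estimating from the baseline alone guarantees that enhancement
  cannot leak into the field. Because ROI percent change is a ratio of
  means over the same voxels, it is in fact invariant to any static
  multiplicative field — correction matters for difference images and
  visual comparison, not for the extracted curves.
* **Smoothing** (`smooth_series`): separable Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in mm, converted to
  voxels through the voxel size; FWHM 0 is the identity. Default 0.1 mm.
* **Percent change** (`extract_roi_timeseries`): per region and frame,
  $100\,(\overline{I}_{ROI} - \overline{B}_{ROI})/\overline{B}_{ROI}$ —
  the ratio of ROI means rather than the mean of voxelwise ratios, which
  is considerably more robust to voxel noise. Whether percent change is
  taken at voxel or ROI level is a genuinely open choice; this one is the
  package's.
* **Difference images** (`difference_image`): voxelwise $I - B$ for
  presentation and per-frame inspection.

Voxel indices are 1-based (R convention); masks must share the volume's
grid exactly — no resampling is implemented.

## The DCE phantom

`generate_dce_phantom` builds a 4D series whose enhancing regions follow
the logistic model exactly: each region voxel's noiseless time course is
$B(x)\,(1 + y(t)/100)$, with $y(t)=0$ for $t \le 0$ (pre-infusion).
Corruptions are applied in the order enhancement → multiplicative bias
(anatomy frame) → per-frame translation → additive Gaussian noise, i.e.
the exact inverse of the correction chain.

Defaults and their reasons:

* **Grid**: $32^3$ voxels at $0.1 \times 0.1 \times 0.15$ mm, 12-min
  frames, 3 baseline frames, 18 frames total (baselines plus 180 min of
  post-infusion imaging). The reduced grid keeps a full pipeline run in
  seconds; geometry scales through the spec.
* **Baseline texture**: the baseline is multiplied by a smooth
  deterministic pattern (sum of three cosines, amplitude 0.15). A uniform
  background would make translation estimation ill-posed — a uniform
  enhancement block is shift-invariant under any SSD-type criterion — while
  the texture cancels exactly in ROI percent change.
* **Bias**: a quadratic multiplicative profile, `bias_amplitude = 1.1`
  meaning up to +10 % at the corners; a stand-in for scanner
  non-uniformity, which is never characterized in the field's reports.
* **Motion**: uniform sub-voxel translations of post-baseline frames up to
  `motion_amplitude` voxels; no rotation, matching the registration model.
* **Noise**: additive Gaussian in percent-of-baseline units. Published
  reports give neither raw signal units nor SNR, so phantom noise is a
  free parameter; 1–2 % exercises the estimators at a level where group
  comparisons remain well powered.
* **ROI masks**: `phantom_roi_mask(..., erode = 2)` erodes the enhancement
  territory before extraction. Smoothing and residual sub-voxel motion
  bias the edge voxels of a sharp ROI (a 1-voxel-FWHM kernel removes
  roughly $0.17\sigma$-worth of enhancement per region face); interior
  placement mirrors how anatomical ROIs are drawn conservatively inside a
  structure.

What passing phantom tests does *not* show: the phantom has no MR physics
(relaxivity, flip-angle effects), no transport PDE (enhancement is imposed,
not diffused), no anatomy, and additive Gaussian rather than Rician noise.
It validates the estimators' arithmetic and their robustness to the modeled
corruptions, not acquisition realism.

## AQP4 polarization and coverage

`polarization_index` implements the endfoot-referenced threshold analysis:
the threshold is the **median** AQP4 intensity over the perivascular
region; `aqp4_area_pct` is the percentage of the analysis region at or
above it (ties count as endfoot-level expression, per the standard
definition); polarization is the complement, so
`polarization_pct + aqp4_area_pct == 100` holds exactly by construction.
Adding a constant to every pixel moves the threshold with the data and
changes nothing.

Geometry choices that the field leaves open, fixed here as defaults:

* the perivascular region is a 1 µm annulus immediately outside the
  endothelially delineated vessel (`delineate_vessel`: threshold on the
  CD31 channel, largest connected component, filled contour — a
  reproducible stand-in for manual delineation);
* the analysis region is the whole image minus the vessel, configurable;
* cross-section profiles (`vessel_line_profile`) are sampled along a
  recorded 4 µm axis with bilinear interpolation and normalized to the
  mean of a recorded background patch — recorded, not random, because
  reproducibility demands the choice be stored.

The synthetic vessel image (`generate_vessel_image`) realizes a requested
polarization by construction: ring pixels sit exactly at the perivascular
median, and the requested fraction of the analysis region is placed
strictly below it, up to one-pixel discretization (the unstained
background patch counts toward the below-median pool). At a target of
100 % the ring itself (≲1 % of the region) stays at the median, so the
realizable maximum is slightly below 100 — recovery is still within the
2-point validation band. With `noise_sd > 0`, set `aqp4_high` above
`aqp4_perivascular`, otherwise noise blurs the deliberate ties at the
median.

## Assays

* **ELISA** (`fit_standard_curve`, `interpolate_concentration`): the
  four-parameter logistic is the kit-standard model and the default; a
  linear fit is the fallback when standards are non-monotone. Samples are
  interpolated by the closed-form inverse and multiplied by their dilution
  factor; out-of-range samples are flagged, never extrapolated. The
  bundled standard series are the kit definitions: 0–2000 pg/ml (total
  tau) and 0–1000 pg/ml (phospho-tau), two-fold dilutions above blank.
* **Blood contamination** (`blood_contamination`): percent ratio of CSF to
  volume-matched whole-blood absorbance at 417 nm (haemoglobin Soret
  band). The oft-quoted 0.0001 % detection floor depends on
  spectrophotometer noise and is documentation, not an enforced limit.
* **Ratios** (`homogenate_ratio`, `replicate_ratio`, `region_ratio`):
  ratios are formed per animal/replicate first and averaged after — the
  mean of ratios, not the ratio of means, which matters whenever scatter
  is not negligible. SEM propagation is first-order Taylor.
* **qPCR** (`delta_delta_ct`): textbook $2^{-\Delta\Delta C_t}$ with the
  mean of the reference genes; invariant to machine offsets by
  construction.

## Group statistics

`group_compare` wraps the four designs used across such studies (unpaired
t-test, one-way ANOVA, two-way ANOVA, and balanced repeated-measures
two-way ANOVA with animal as the error stratum) over `stats::aov` /
`stats::t.test`, with Bonferroni-corrected post hoc group contrasts at
each time point using the design's pooled error term. Unbalanced
repeated-measures tables are rejected with the missing (animal, time)
cells listed, rather than silently approximated. The repeated factor
defaults to time alone; time-by-region designs are expressed by calling
per region.

## Validation suite: sizes and expectations

The shipped tests regenerate everything from code; the problem sizes are
chosen so the whole suite runs in well under a minute:

* sigmoid recovery: every bundled reference parameter row, noiseless, to
  1e-6 relative; 200 seeded repetitions at 1 % noise and 16 frames for
  bias (< 2 %) and CI coverage (≈ 90–99 %);
* a grid-search oracle (13³ parameter grid, 50 seeded noisy datasets)
  that the optimizer must never lose to;
* an end-to-end 32³ phantom with ±2-voxel motion, +10 % quadratic bias and
  1 % noise, recovered within 1 % absolute after the full chain;
* polarization targets {0, 25, 50, 80, 100} recovered within 2 points;
* exact assay round trips at zero noise;
* ANOVA/t statistics checked against hand-computed sums-of-squares
  decompositions to 1e-8, and the curve-comparison F test's empirical
  size over 200 null repetitions held near its nominal 5 %.

## Known limitations

* Registration is translation-only; rotational motion is neither
  simulated nor corrected.
* The bias model (2nd-order log-polynomial) cannot represent high-order
  shading; ROI percent change is insensitive to this by construction, but
  difference images are not.
* The vessel phantom is a single idealized circular capillary; real
  vessel cross-sections are elliptical, clustered and unevenly stained.
* Group curve fitting pools points, treating repeated measures on one
  animal as independent; this matches the field's reporting convention
  but understates within-animal correlation.
* The ELISA inverse is undefined at and above the fitted upper asymptote;
  such samples must be re-run at higher dilution (they are flagged).
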
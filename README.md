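# glymphkit

Quantification of glymphatic CSF-ISF exchange in the rodent brain: dynamic
contrast-enhanced (DCE) MRI inflow kinetics, perivascular AQP4 polarization
from immunofluorescence, and tau clearance assays — with a synthetic-data
layer that generates every input with known ground truth so the whole
pipeline is testable end to end.

## Who this is for

Groups studying glymphatic function (CSF-ISF exchange and solute clearance)
with intrathecal-contrast MRI and histology in mice: the package turns raw
4D image series, two-channel micrographs and plate-reader tables into the
standard regional statistics of the field, and lets you validate each step
on phantoms before trusting it on animals.

## The models at the core

**Inflow kinetics.** Regional T1-weighted enhancement after cisterna magna
Gd-DTPA infusion, expressed as percent change from the averaged baseline,
follows a sigmoid

y(t) = Intensity_Max / (1 + exp((Time_50 − t)/Slope))

with plateau `Intensity_Max` (%), half-maximum time `Time_50` (min) and
rise scale `Slope` (min). Each region's **penetration efficiency** is
`Intensity_Max / Time_50` (%/min). Fits are Levenberg–Marquardt least
squares with multi-start; intervals are asymptotic 95% CIs, and the
efficiency CI comes from the delta method. Groups are compared by
extra-sum-of-squares F tests.

**Preprocessing.** The DCE chain is: rigid translation alignment to the
averaged baseline (robust, enhancement-trimmed gradient descent), division
by a baseline-derived intensity non-uniformity field (2nd-order
log-polynomial), isotropic Gaussian smoothing (default FWHM 0.1 mm),
difference images `D = I − B`, and ROI percent-change extraction.

**AQP4 polarization.** The threshold is the median AQP4 intensity over the
perivascular (endfoot) annulus; `AQP4 % area` is the share of the region at
or above it, and polarization is the complement — the share of tissue
expressing less AQP4 than the endfeet. Vessel coverage is the
AQP4-positive share of the endothelially delineated vessel area.

**Assays.** Four-parameter-logistic ELISA standard curves with flagged
(never extrapolated) back-calculation, 417 nm blood-contamination ratios,
mean-of-per-animal regional ratios, 2^−ΔΔCt expression, and infusion
dose/duration arithmetic.

## Worked example

A 32³ phantom whose caudal-cortex region enhances with known parameters
(Intensity_Max 60.17 %, Time_50 39.66 min, Slope 10 min), corrupted with
±2-voxel frame motion, a +10 % quadratic bias field and 1 % noise, then
pushed through the full chain:

```r
library(glymphkit)

ph <- generate_dce_phantom(phantom_spec(
  list(cuboid_region("caudal_cortex", c(16, 16, 16), 5,
                     intensity_max = 60.17, time_50 = 39.66, slope = 10)),
  noise_sd = 1, motion_amplitude = 2, bias_amplitude = 1.1, seed = 7))

reg <- register_series(ph$volume)                 # undo frame motion
bc  <- bias_correct(reg$volume)                   # divide out the field
sm  <- smooth_series(bc$volume, fwhm_mm = 0.1)    # 0.1 mm FWHM Gaussian
ts  <- extract_roi_timeseries(sm, phantom_roi_mask(ph, erode = 2))

fit <- fit_sigmoid(ts)
fit
#> Sigmoidal inflow fit (best-fit value [95% CI]):
#>   Intensity_Max: 60.35 %  [60.28, 60.42]
#>   Time_50:       39.58 min [39.48, 39.68]
#>   Slope:         10.04 min [9.951, 10.13]
#>   n = 15, R^2 = 1.0000, residual SS = 0.1129

penetration_efficiency(fit)
#> Penetration efficiency: 1.52 %/min [95% CI 1.52, 1.53]
```

The fit recovers the generating parameters through the corruption, and the
penetration efficiency matches the truth (60.17/39.66 = 1.52 %/min): a
high-inflow region fills fast and plateaus high. Low-inflow regions (e.g.
a rostral cortex at Intensity_Max ≈ 7.4 %, Time_50 ≈ 77 min) score an
order of magnitude lower, ≈ 0.10 %/min.

Ready-made end-to-end experiments (inflow, clearance, polarization) run via
`run_experiment()`, writing tidy CSVs and a seed-stamped JSON log:

```r
run_experiment(list(experiment = "inflow", output_dir = "out", seed = 1))
```

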
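---
title: "Depth-resolved polarized reflectance analysis with oprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved polarized reflectance analysis with oprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oprs)
library(dplyr)
```

## The measurement and the problem

Oblique polarized reflectance spectroscopy (OPRS) records elastic-scattering
spectra of epithelial tissue through a fiber probe with obliquely polished
detection fibers at three source–detector separations, each duplicated with a
co-polarized ("parallel": `BF1`, `BF2`, `BF3`) and a cross-polarized
("perpendicular": `BF1per`, `BF2per`, `BF3per`) detection film. Photons that
keep the illumination polarization have scattered few times and therefore
come from shallow depths; increasing fiber separation and depolarization both
push the sampled volume deeper. The analysis task is binary diagnostic
classification between four histopathological categories of oral mucosa —
normal, benign (clinically suspicious but histologically normal), mild
dysplasia (MD) and severe dysplasia (SD) — from 93 measurements of 25
patients, with the confounder that benign and dysplastic lesions both carry a
strongly scattering, highly variable superficial keratin layer.

This package implements the full analysis pipeline and, because no clinical
spectra are distributed, a generative forward model that simulates complete
cohorts with the statistical structure the pipeline assumes. Every stage is a
plain function from tibbles to tibbles:

```{r pipeline, eval = FALSE}
cohort <- simulate_cohort(seed = 1)
normalized <- normalize_cohort(
  cohort$spectra, cohort$manifest, cohort$calibrations, cohort$probe
)
factors <- patient_factors(normalized, cohort$manifest)
standardized <- apply_standardization(normalized, cohort$manifest, factors)
channels <- build_channels(standardized)
tasks <- run_all_tasks(channels, cohort$manifest, task_config(seed = 1))
```

## The forward model

A measurement is modelled as a two-layer epithelium on a semi-infinite
stroma. Each channel `c` has a cumulative depth response

$$W_c(z) = 1 - \exp(-z / z_{0,c}),$$

the fraction of its saturated signal collected above depth $z$. The channel
spectrum is a depth-weighted mixture of three layer spectra,

$$I_c(\lambda) = W_c(z_{ker})\,S_{ker}(\lambda)
  + [W_c(z_{tot}) - W_c(z_{ker})]\,S_{epi}(\lambda)
  + [1 - W_c(z_{tot})]\,S_{str}(\lambda)\,H(\lambda),$$

where the layer spectra are power laws in $\lambda/600\,$nm — keratin with a
steep blue-slope exponent (4–4.5), viable epithelium and stroma with
exponent 1 — and $H(\lambda) = \exp(-c_{Hb}\,\varepsilon(\lambda))$ models
oxyhemoglobin absorption in the stroma with $\varepsilon$ a two-Gaussian
approximation of the visible extinction spectrum (peaks 542 and 576 nm,
width 12 nm, alpha band at 0.85 relative amplitude). A parametric shape was
deliberately chosen over a tabulated extinction curve: it keeps the package
self-contained and preserves exactly the spectral feature the pipeline uses
(the 576/610 nm ratio and absorption-band wavelengths), which is all the
classification stage sees. No photon-transport simulation is attempted; the
exponential saturation form is an empirical description of how overlapping
illumination/collection cones integrate signal with depth.

The saturating-exponential scale is parameterized through the depth at which
a channel reaches 90% of its saturated signal, $z_0 = d_{90}/\ln 10$, with
default $d_{90}$ of 750/900/1100 µm for `BF1`–`BF3` and 1200/1250/1400 µm
for the perpendicular fibers — perpendicular channels probe deeper because
polarization is gradually randomized with depth.

Tissue classes differ in (units µm for thicknesses, dimensionless
amplitudes):

```{r params}
tissue_class_params()
```

The defaults encode: epithelial thickening with dysplasia progression (total
thickness means 426/504/701 µm for benign/MD/SD), an epithelial scattering
amplitude increasing with grade, and a keratin layer that is brightest and —
critically — most variable in thickness in the benign class. The normal
class (total 300 ± 50 µm, thin keratin) has no direct literature anchor in
the modelled cohort and was fixed once at values a histologist would accept
for normal oral mucosa. With these defaults the noiseless class-mean
parallel intensities order benign > SD > normal, the qualitative pattern the
classification stage exploits, and the benign-versus-dysplasia contrasts are
the hard ones because the class means are close while benign variance is
large.

Interpatient intensity scale is lognormal with log-sd 0.4, shared across all
of a patient's measurements — this is the nuisance variable standardization
must remove, and 0.4 produces the several-fold pre-standardization spread
such probes show in practice. Instrument wrapping inverts the preprocessing
equations exactly (white/dark calibration per session, integration time,
per-channel throughput `P` and collection area `A`, and the depolarization
coefficient), then applies multiplicative Gaussian noise (default 2%).

What the simulation does *not* emulate: anatomical-site spectral
differences (site labels are metadata only; real oral anatomy matters),
probe-pressure effects, per-lesion correlation of abnormal measurements
beyond the shared patient scale, wavelength-dependent noise, and any
deviation of real tissue from the three-component power-law mixture.
Passing tests therefore demonstrate that the *pipeline* is correct and
well-behaved under the assumed data structure — not that the clinical
performance figures would be reproduced on new patients.

## Preprocessing and standardization

Raw counts are converted to comparable reflectance by dark subtraction,
white-standard normalization, and correction for integration time,
throughput and collection area; perpendicular channels additionally divide
by the depolarization coefficient
$D = (I_{white,\parallel} - I_{dark,\parallel}) /
(I_{white,\perp} - I_{dark,\perp})$, which compensates the white standard
not being a perfect depolarizer. Two choices were genuinely open:

* **Spectral versus integrated D.** The correction is written spectrally, so
  the default computes $D(\lambda)$ per wavelength; a scalar mode (ratio of
  integrated intensities) is available via `spectral = FALSE`.
* **Negative reflectance.** Noise can push dark-subtracted values slightly
  negative. They are retained — clipping at zero would bias every downstream
  mean upward — and a warning fires if more than 1% of points are negative.

Standardization removes the per-patient scale: $S_i = N_{mean}/N_i$ with
$N_i$ the integrated intensity (trapezoid, 450–750 nm) of the patient's
averaged normal-site spectrum and $N_{mean}$ the same quantity for the grand
average over all normal spectra. Since no single channel is canonical for
defining $N$, the default sums all six channels' integrated intensities; the
`channels` argument restricts it, and the same definition necessarily
applies to both $N_i$ and $N_{mean}$. Averaging precedes integration for
patients with several normal measurements. After standardization every
patient's integrated normal intensity equals $N_{mean}$ exactly; spectral
shape is untouched. Patients with no normal measurement are a hard error by
default (an $S_i = 1$ fallback exists for external data).

## Feature engineering

Twenty-seven combination spectra are formed per measurement (9 families × 3
combinations): the six fiber channels, polarization-gated differences
(parallel − paired perpendicular, isolating shallow photons), diffuse sums,
parallel/perpendicular ratios, adjacent-fiber differentials in each
polarization, differential ratios, and gated ratios. Each exists
unnormalized and area-normalized (divided by its trapezoid integral, to
isolate spectral shape from magnitude). Per binary task, the most
discriminatory wavelength $\lambda^*$ of each combination × variant is the
argmax of the per-wavelength Welch t-statistic between the two classes,
computed across *patient-level* mean spectra so interpatient variation is
the denominator; ties break toward the shortest wavelength. The feature
vector per measurement has 120 entries: 27 spectral means, 27 intensities at
$\lambda^*$, and the 576/610 nm intensity ratio of the six fiber channels
(hemoglobin absorption magnitude), each in both variants. The
area-normalized 576/610 ratio is algebraically identical to the
unnormalized one (the scale cancels); the catalogue keeps both entries so
the feature count and layout remain as designed, and the redundancy is
asserted in the tests rather than hidden.

Numerical details: ratio spectra are masked (`NA`) at wavelengths where the
denominator is within $10^{-6}$ of zero relative to its median magnitude,
and masked points are excluded from means, integrals and argmax; spectral
means are plain grid averages (equivalent to integral/width on the uniform
grid); band summaries split 450–750 nm into 20-nm bands whose last band
spans 730–750 nm (21 points), with percentages of 27 rounded to integers.

## Classification, validation, and the permutation control

Per task, features are ranked by greedy minimum-redundancy
maximum-relevance selection (MID difference criterion; MIQ available), with
mutual information estimated by a plug-in histogram after 3-bin
equal-frequency discretization; ties break on feature name so column order
is irrelevant. The feature-set size grows along the ranking until the
ensemble's out-of-bag AUC on the training data stops improving by at least
0.01, capped at 8 features. Out-of-bag error is the package's
cross-validation estimate here: it is a bootstrap-resampling estimate
obtained from a single fit per candidate size, which keeps the permutation
test (100 complete pipeline reruns) tractable without changing the
stopping logic.

The classifier is a seeded probability random forest (`ranger`, 500 trees,
`mtry = floor(sqrt(p))`, single-threaded for reproducibility) — no
hyperparameters are tuned. Validation is grouped leave-one-patient-out:
one fold per patient, all of a patient's measurements held out together, so
no patient ever contributes to both training and test. Out-of-fold
positive-class probabilities feed a nonparametric ROC (Mann–Whitney AUC,
ties counted ½) and an operating point maximizing Youden's J, with J-ties
resolved toward higher sensitivity and percentages reported as whole
percent.

**Where selection happens is the central leakage decision.** The default
(`lambda_policy = "global"`) computes $\lambda^*$ and the mRMR ranking once
on the full task data before cross-validation — this matches how a single
per-task set of discriminatory wavelengths is usually reported, but it lets
label information leak into the features, so out-of-fold AUCs are
optimistic. The `"per_fold"` policy recomputes $\lambda^*$, the ranking and
the size selection inside every training fold and is the honest-estimate
mode. The permutation test quantifies exactly this optimism: labels are
shuffled at the measurement level (class counts preserved; a patient-level
variant exists), the *entire* pipeline — including wavelength selection and
mRMR — is rerun per shuffle under whichever policy is in force, and a task
passes when its real AUC exceeds the shuffled mean by more than two
shuffled standard deviations. The two-sd rule is this package's
operationalization of "clearly above the shuffled band". Under the global
policy the shuffled mean sits well above 0.5 (the leak, made visible);
under the per-fold policy it sits at chance.

## Phantom depth calibration

The probing depth of each channel is measured by scanning a scattering
phantom: transmission through dilute suspensions gives
$\mu_s = -\ln(T)/L$ (the dimensional reading of the transmission relation),
converted to reduced scattering via $\mu_s' = \mu_s(1-g)$ with $g = 0.752$;
a linear fit of $\mu_s'$ against concentration is inverted to find the
concentration (≈2.6%) reaching the stromal target $\mu_s' = 2\,$mm⁻¹. The
channel's integrated intensity versus phantom thickness (0–2500 µm in 50-µm
steps) saturates; the reported probing depth is where the curve first
reaches 90% of its saturated level, refined by linear interpolation between
bracketing grid points.

The saturated level itself must be estimated. A tail mean (last 10% of grid
points) underestimates the plateau whenever the curve is still rising at
the end of the scan — for the deepest channel (nominal 1400 µm) the curve
reaches only ≈98% of its asymptote at 2500 µm, and a tail-mean plateau
would misplace the 90% depth by more than 100 µm. The default therefore
fits a saturating exponential $I(z) = I_\infty(1 - e^{-z/\zeta})$
(Levenberg–Marquardt) and uses its asymptote, which recovers exponential-
family curves exactly across the whole calibrated range; `plateau = "tail"`
remains available for curves that saturate well inside the scan. For
measured curves that the exponential cannot describe, the fit falls back to
the tail mean automatically.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds: the cohort seed fixes
tissue draws, patient scales, calibration jitter and noise; the analysis
seed fixes every forest and the permutation shuffles (per-shuffle seeds are
derived offsets). Identical seeds give byte-identical manifests, spectra
and result tables.

The packaged test suite exercises the pipeline at the scales it is designed
for: the full 93-measurement, 25-patient default cohort for the eight-task
analysis and a 100-shuffle permutation test on one task, plus a smaller
36-measurement cohort for unit-level properties and a 24-measurement
null cohort (all classes drawn from identical tissue parameters) for the
chance-level permutation check — sizes chosen so the complete analysis runs
on a laptop in minutes while every statistical claim is still tested at
n = 100 shuffles.

## Known limitations

* The forward model is a mixture description, not radiative transport;
  absolute reflectance levels are arbitrary units.
* Site labels do not modulate spectra by default, so anatomy-stratified
  analyses cannot be rehearsed on the defaults.
* The global selection policy's AUCs are optimistic by construction; use
  `per_fold` for honest point estimates and the permutation report when
  quoting significance.
* With very few positive measurements per task (the smallest default task
  has 10), per-fold estimates are noisy; the permutation band, not the AUC
  alone, is the meaningful statement.
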
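---
title: "Separating vascular and neural contributions to BOLD variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating vascular and neural contributions to BOLD variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfa)
```

## The problem

The BOLD signal is a composite of neural activity and vascular physiology.
With ageing, vascular reactivity declines, so an apparent age-related drop
in task activation can reflect blood-vessel physiology rather than
neuronal function. The resting-state fluctuation amplitude (RSFA) — the SD
of the nuisance-cleaned, 0.01–0.08 Hz band-passed resting BOLD signal at a
voxel — is a practical proxy for vascular reactivity: it needs no
breath-hold or gas challenge, which matters in older cohorts. Dividing a
task beta by the voxel's RSFA ("haemodynamic scaling") discounts vascular
gain, so what survives scaling is more plausibly neural.

This package implements that whole chain — RSFA mapping, task-GLM scaling,
cardiac vascular indices from pulse waveforms, band-limited sensor
variability, MDL-ordered ICA data reduction, and three-variable mediation
models with bias-corrected bootstrap inference — together with a
synthetic-cohort generator that plants known ground truth, so every claim
the pipeline makes can be tested end to end without any data download.

## The generative model

Each synthetic participant carries two latent factors:

* **V**, a vascular gain: `V = intercept + slope_V * age + noise`,
  truncated at 0.05 (default slope −0.01/year, noise SD 0.12). V drives
  resting BOLD fluctuation amplitude, heart rate (negatively) and
  heart-rate-variability modulation depth.
* **N**, a neural amplitude: same linear-in-age form (default slope
  +0.004/year, noise SD 0.10). N drives band-limited sensor variability
  and the neural part of the task response.

The BOLD grid (default 16×16×8 voxels, 250 volumes, TR 1.97 s — a
desk-scale stand-in for a 3 mm EPI acquisition) is partitioned into slabs:
CSF, WM, and grey matter split into a *vascular* region (resting amplitude
∝ V; task amplitude ∝ V), a *neural* region (task amplitude ∝ N·V) and a
*null* region. The true unscaled task beta at a responsive voxel is
therefore the neurovascular product, and an RSFA-scaled beta tracks N
alone — which is exactly the dissociation the scaling analysis is supposed
to deliver, and what the end-to-end test asserts.

Three modelling choices deserve comment:

* **Resting amplitude in neural voxels** is `V · (1 + 0.3·(N − 1))`, not
  `V · N`. Resting fluctuations are treated as vascular-dominated with a
  minor neural contribution. A fully multiplicative resting amplitude
  would make scaling divide the neural effect out of its own task map,
  defeating the method by construction; the 0.3 weight keeps a visible
  neural imprint on RSFA without that degeneracy.
* **Band-limited noise is calibrated against the analysis filter.** White
  noise is band-passed, then rescaled so that its SD *after one further
  pass* through the same zero-phase filter equals the target. The RSFA
  pipeline band-passes the data once, so planted amplitudes are recovered
  exactly by construction, up to what the nuisance regression removes.
* **Ectopic beats** are planted by displacing a configured fraction
  (default 2%) of beat times by ±40% of the local interbeat interval —
  large enough to trip a 3-SD criterion, small enough to leave the series
  analysable.

Ages are drawn uniformly over 18–88, matching a design that samples
roughly uniformly across deciles. The cohort default is 335 participants.
Effect sizes of age on V and N are free parameters of the configuration,
not claims about physiology; the defaults give standardized age effects in
the range typically reported for vascular decline.

## RSFA estimation

`build_nuisance()` assembles 17 regressors: intercept, linear and
quadratic trends, mean WM and mean CSF signal, six motion parameters and
their first differences (zero-padded at the first sample). Near-collinear
columns (|r| > 0.999) are pruned with a warning so degenerate inputs
(constant motion) stay estimable. `clean_and_filter()` residualizes
against this design *before* filtering — the order the field's standard
pipeline lists, exposed as two steps so the alternative order can be
composed — and then applies a 4th-order Butterworth band-pass
forward-backward (zero phase; 8th-order magnitude response). `compute_rsfa()`
takes the voxelwise SD with the n−1 denominator.

Numerical behaviour worth knowing:

* An in-band unit sinusoid comes through with SD 1/√2 to within 2%; probes
  at 0.004 Hz and at 0.2 Hz (the highest frequency a 1.97 s TR can carry)
  are attenuated by more than 20 dB.
* The nuisance regression removes a few percent of genuine in-band
  variance (trend terms absorb some 0.01 Hz power, and 17 of ~250 degrees
  of freedom go to the design). Planted amplitudes are recovered to within
  5% in the default geometry; correlations across participants — what the
  group analyses consume — are unaffected.

## Task scaling

`fit_task_glm()` uses the canonical double-gamma HRF (peak 6 s, undershoot
16 s, 1/6 ratio; unit peak for an isolated event) convolved with the event
train on a 0.1 s grid, plus intercept and linear drift. Temporal and
dispersion derivatives are omitted: the generator produces canonical
responses, so the derivatives would be exactly zero-weighted nuisance. The
default synthetic event train jitters stimulus-onset asynchrony over
6–14 s; a strictly periodic train at these durations is nearly collinear
with the intercept and makes betas unstable.

`scale_betas()` divides beta by RSFA voxelwise, flooring at the 1st
percentile of in-mask RSFA: voxels below the floor leave the mask rather
than being divided, which keeps the ratio numerically stable.
`contrast_scaled_unscaled()` z-scores scaled and unscaled maps across
participants per voxel before differencing — the two are on different
units (ratio versus raw), and the difference GLM needs a common scale.
Family-wise error over voxels is controlled by permutation of the max-|t|
statistic (default, 1000 seeded permutations) or Bonferroni; permutations
shuffle map rows jointly against the whole design, which is exact under
the global null and mildly conservative for covariate-only effects.

## Cardiac indices

`detect_beats()` finds local maxima above an adaptive threshold — half the
spread between the 98th percentile and the median — with a 300 ms
refractory period. The high percentile anchors the threshold to beat
amplitude even for waveforms that spend most samples near baseline (sparse
pulse trains, ECG); lower percentiles sit in the noise floor there and let
noise peaks through.

`reject_outliers_iterative()` implements the iterated SD criterion: pass 1
estimates mean and SD after setting aside the single most extreme value
(so one gross artefact cannot mask itself), removes everything beyond
±3 SD, and subsequent passes use the full remaining sample until nothing
moves. The "set aside the most extreme value" step applies to pass 1 only;
removal provenance (index, value, pass) is kept. The procedure is
idempotent, and never removes a value inside ±3 SD of the final sample.

`mean_hr()` counts intervals per full 60-s window and averages; a trailing
partial window of at least half the window length is kept with its count
scaled to a per-minute rate, shorter remainders are discarded.
`hrv_band_power()` spline-interpolates the tachogram to uniform 4 Hz,
removes a linear trend, and integrates a Welch PSD (64-s Hann segments,
50% overlap) over the LF (0.05–0.15 Hz) or HF (0.15–0.4 Hz) band, in ms².
Whether to log-transform HRV powers before the PCA step is left to the
user; `vascular_pca()` standardizes columns (correlation-matrix PCA) and
orients PC1 so the HF-HRV loading is positive — higher score, better
vascular function — which on the synthetic cohort makes PC1 correlate
positively with the true V at r > 0.95.

## Sensor-band variability

`band_sd()` band-passes each channel (same zero-phase Butterworth family)
and takes the SD of the raw filtered series — not its Hilbert envelope —
per channel, for the six standard bands (subdelta 0.01–0.08, delta 1–4,
theta 4–8, alpha 8–13, beta 13–30, gamma 30–80 Hz; the 0.08–1 Hz gap is
deliberate). A very low band at a kHz rate would make the IIR filter
ill-conditioned, so the signal is first decimated by repeated zero-phase
half-band low-pass and downsampling until the band occupies a sensible
fraction of the bandwidth; the subdelta band needs records of 100 s or
more to be meaningful. `flag_artifact_components()` implements the
correlation-threshold flagger: a component is artifactual if its time
course correlates with a reference channel at ≥3× the SD of all such
correlations, with topographic confirmation (≥2× the SD of spatial
correlations with a template) required for eye-channel hits. The
thresholds are relative, so the rule needs a reasonable number of
components (enforced minimum 5; it is calibrated for dozens).

## Component reduction

`mdl_order()` applies the classic Rissanen/Wax–Kailath criterion to the
eigenvalues of the data covariance, treating the smaller matrix dimension
as the signal dimension and the larger as the sample count. The
i.i.d.-correction used by some group-ICA toolboxes subsamples the data
with unspecified parameters; the classic form is the default here and
behaves well on planted ranks (rank 3 at SNR 10 is found in ≥9/10 seeds;
white noise stays at order ≤2).

`ica_decompose()` whitens to K dimensions and runs fixed-point ICA (tanh
contrast, symmetric decorrelation, tolerance 1e−6, up to 1000 iterations)
via the fastICA algorithm. Permutation and sign are fixed
deterministically: components are ordered by explained variance and each
source map's skewness is made positive; participant loadings (mixing
columns) are z-scored independently per component. Symmetric fixed-point
iterations on small samples can cycle just above a tight tolerance, so
non-convergent fits are restarted from a fresh seeded rotation, relaxing
the tolerance tenfold after every two failed attempts (eight attempts,
then a convergence error). Identical seeds give bitwise-identical models.

## Mediation

`fit_paths()` z-scores all variables (covariates included) and fits the
three OLS regressions of the standard three-variable path model — `M ~ IV`,
`DV ~ IV`, `DV ~ M + IV` — with the covariates (default gender and
handedness) in every model, returning standardized paths a, b, c, c′ and
the indirect effect ab = a·b. With identical covariates across models,
ab = c − c′ holds to numerical precision, and the test suite asserts it on
random data.

`bc_bootstrap_ci()` resamples whole participant rows with replacement
(default B = 10,000; the heavy simulations in the tests use B = 1000),
refits all paths per draw in compiled code driven by R's RNG, and forms
bias-corrected percentile intervals: with z₀ the normal quantile of the
fraction of bootstrap estimates below the point estimate, the endpoints
are the bootstrap quantiles at Φ(2z₀ ∓ z₁₋α/₂). Significance is declared
when the 99% CI excludes zero. Standardization happens once, on the
observed sample; draws are refit without re-standardizing. The reported z
is the point estimate over the bootstrap SE, and p is the smallest
conventional level (0.05, 0.01, 0.001) at which the BC interval excludes
zero — CI-consistent by construction, and not claimed to match any
particular toolbox's analytic z. Note that a BC interval need not contain
the point estimate when the bootstrap distribution is strongly
median-biased; for symmetric distributions it coincides with the
percentile interval.

`classify_effect()` labels a significant indirect effect *mediation* when
|c′| < |c| with sign(ab) = sign(c) (controlling the mediator weakens the
direct effect) and *suppression* when |c′| > |c| (controlling the mediator
strengthens it); `proportion_mediated()` reports 100·|ab/c| percent.

## What the tests do and do not show

The synthetic cohort plants exactly the statistical structure the analyses
assume: linear age effects, Gaussian noise, canonical HRF responses,
sinusoidal HRV modulation, disjoint focal sensor topographies. Passing
tests therefore demonstrate that the estimators are correct and correctly
wired together — RSFA recovers planted amplitudes, scaling removes a
vascular-only age effect (the unscaled group map shows t < −2 across the
vascular region; after scaling 90%+ of it is null) while a true neural
effect survives, the BC bootstrap covers a planted indirect effect at its
nominal 99% rate and keeps type-I error near 1%. They do not show that
real resting fluctuations are vascular, that real HRV indexes vascular
health, or that real cohort effects are linear in age; respiration and
CO2 dynamics, scanner artefacts, anatomy and head motion correlated with
age are all absent from the generator on purpose.

Problem sizes in the shipped tests and acceptance script are chosen at
desk scale: a 16×16×8 grid with 100 participants for the scaling
experiment, 100 replicate cohorts (n = 335, B = 1000) for bootstrap
coverage, 500 for the null-rejection rate, 40-participant cohorts for the
latent-recovery checks. These sizes put Monte-Carlo error comfortably
inside the asserted margins.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_participants = 60, seed = 1,
                        grid_shape = c(8L, 8L, 4L), n_volumes = 150L)
coh <- generate_cohort(cfg)

# vascular index from pulse waveforms
feats <- t(sapply(seq_len(60), function(i)
  cardiac_features(simulate_physio(coh[i, ], cfg))))
hrv_pc1 <- vascular_pca(feats)$scores[, 1]

# RSFA summary over the vascular region
rsfa_mean <- sapply(seq_len(60), function(i) {
  run <- simulate_rest_bold(coh[i, ], cfg)
  map <- compute_rsfa(run)
  mean(map$values[run$truth$labels == "vascular"])
})

# does the vascular index mediate the age effect on RSFA?
mediate(data.frame(age = coh$age, hrv = hrv_pc1, rsfa = rsfa_mean,
                   gender = coh$gender, handedness = coh$handedness),
        iv = "age", m = "hrv", dv = "rsfa", B = 2000, seed = 2)
```

The printed result reports standardized paths with 99% BC intervals, the
mediation/suppression classification, and the proportion mediated.
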
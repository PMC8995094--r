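---
title: "Methods: contact-site morphometry, Ca2+ kinetics and puncta quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-site morphometry, Ca2+ kinetics and puncta quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsquant)
```

This vignette explains the models and estimators in `mcsquant`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Membrane morphometry

### Gap distance

A cortical-ER (cER) structure is scored from two traced polylines in
calibrated nm coordinates: the plasma membrane (PM) and the apposed cER
membrane. `gap_distance()` defines the ER-PM gap as

1. resample the cER trace at uniform arc-length spacing (default: the
   recorded pixel size, 0.5 nm at high-magnification EM, emulating
   per-pixel measurement);
2. for each resampled cER point, take the minimum Euclidean distance to the
   PM *polyline* — true point-to-segment distance, never point-to-vertex;
3. average over cER points.

Distances are measured from the cER trace to the PM and not symmetrised:
the cER trace delimits the structure being scored, while the PM trace is
deliberately drawn longer. An alternative convention — raster geodesic
distances on the pixel grid — differs from nearest-point distances by at
most a sub-nm amount at these scales; the nearest-point definition is used
because it is well defined off-grid and is checkable against a brute-force
oracle (the test suite verifies agreement within 0.05 nm against a
0.01 nm-step point-sampled sampler on curved fixtures).

Properties worth knowing: the estimator is exact for parallel traces and
concentric arcs; it is invariant under rigid transforms; vertex jitter of
1 nm perturbs the mean by well under 3% at gaps of ~17 nm because errors
average out over the resampled points.

### Length and cleft volume

`cer_length()` is the arc length (sum of segment lengths) of the long-axis
polyline when one is provided (`membrane == "AXIS"` rows), else of the cER
trace. Tracing jitter *inflates* chord lengths by roughly
`sqrt(1 + 4*sigma^2/spacing^2)` per segment; at the 10 nm vertex spacing of
a careful hand trace and sigma = 1 nm this is ~2%, which is why the
recovery tests place vertices 10 nm apart rather than densely.

`cleft_volume()` models the cytosolic cleft as a cylinder of **diameter**
equal to the cER length and height equal to the gap: V = pi (L/2)^2 g.
The diameter convention is isolated in this one function so it can be
swapped for a radius convention if preferred. `cortical_filter()` applies
the strict g < 30 nm criterion that defines cortical ER; the threshold is
applied to the per-structure *mean* gap.

`condition_summary()` reports n, mean and sample s.d. (n-1 denominator)
per group, and also the s.e.m., explicitly labelled, since published
figures mix the two. Volumes are averaged per structure — the mean of the
per-structure volumes, never the volume of the mean structure, which would
be biased low by Jensen's inequality. `fold_change()` returns the full-
precision ratio of group means plus a 2-significant-figure label.

## 2. The gap plateau of elongated cER

On gap-versus-length scatter data, tether-anchored cER sheets longer than
a few hundred nm cluster at a tether-specific gap. `plateau_gap()` makes
that figure annotation a statistic: the mean gap over structures with
length **strictly greater** than a threshold (default 300 nm; 700 nm and
600 nm are the conventional onsets for the short and long MAPPER tethers
after store depletion). Strict thresholding was chosen over inclusive; at
continuous lengths the difference is measure-zero, but it makes the
monotonicity property (raising the threshold never increases the
subpopulation) exact.

No model-based (change-point or asymptotic-regression) fit is attempted —
the statistic of interest *is* the thresholded mean. Because a thresholded
mean deserves an honest uncertainty, the estimate carries a seeded
nonparametric bootstrap percentile CI (default 2000 resamples). Percentile
bootstrap coverage for a mean of ~100 observations is known to run a
little under nominal (~94% at n = 100); the suite checks 95% ± 3% over 500
replicates. Groups with no qualifying structures return an explicit empty
estimate rather than an error, so grouped pipelines do not crash on sparse
conditions.

## 3. Ratiometric Ca2+ kinetics

### R/R0 traces

`ratio_trace()` subtracts the mean background-ROI intensity per channel,
forms R = (F340 - bg)/(F380 - bg) per frame, and normalises by R0, the
mean R over the baseline window (default: all frames before the first
protocol event). R is invariant under common scaling of both channels and
backgrounds, and the baseline mean of R/R0 is 1 by construction. Frames
whose background-subtracted F380 is non-positive are dropped and counted,
never interpolated — fabricating frames would bias downstream slopes.

### Derivative-guided slope extraction

`slope_from_derivative()` formalises the common "use the first derivative
to pick the regression region" procedure:

1. smooth the trace with a centred moving average of `w` frames (default
   5; the window shrinks symmetrically at segment ends);
2. compute the discrete first derivative (central differences);
3. locate the derivative extremum in the requested direction within the
   segment (earliest on ties — the SOCE rise is the first steep event
   after readmission);
4. take the maximal contiguous run of frames around the extremum where the
   directed derivative is at least `alpha` times the extremum (default
   0.5);
5. fit ordinary least squares **on the raw values** over that run.

Fitting raw rather than smoothed values matters: on a noiseless ramp that
ends in a hard plateau, the smoothed values are corner-contaminated but the
raw values within the selected run lie exactly on the line, so the fitted
slope equals the true slope to machine precision (a property the tests
assert at 1e-9).

`alpha` is an explicit bias-variance dial, and the right value depends on
what the target is:

* For piecewise-linear protocols (the SOCE entry segment) the trace is
  straight wherever its derivative is large, so a wide window is free of
  bias and maximally noise-averaging: `alpha = 0.5` is the default.
* When the target is the *instantaneous* maximal slope of a smooth
  sigmoid, the window must shrink onto the inflection point: for a
  logistic rise A/(1+exp(-k(t-t0))) the OLS slope over the half-max
  derivative region underestimates A k/4 by ~13%, whereas at
  `alpha = 0.95` the bias is ~1%. The logistic checks in the test suite
  therefore run at `alpha = 0.95`. The bias is a property of fitting a
  chord to a curve, not of the implementation.

`entry_rate()` applies the engine (rising, default `alpha`) to the segment
from Ca2+ readmission to the next event; slopes are reported in R/R0 per
second (published work sometimes leaves this unit implicit; here it is
always per second).

### Decay rates: extrusion and Mn2+ quench

Post-removal Ca2+ clearance and Mn2+ quench of the isosbestic 360 nm
signal are exponential decays, and the quantity of interest is a *rate
constant* (1/s), not a chord slope in signal units. For a boundary-peaked
exponential the derivative-fraction window is intrinsically asymmetric and
a linear fit over it underestimates the initial slope by 1 - rT/2 (28% at
the half-max window) — no window width fixes this without destroying noise
averaging. `extrusion_rate()` and `quench_rate()` therefore fit OLS to the
**log** of the baseline-referenced signal:

* extrusion: log(R/R0 - asymptote), asymptote defaulting to the resting
  baseline 1;
* quench: log of F360 normalised to its pre-Mn2+ mean, asymptote 0.

For an exponential, the amplitude-fraction window used (frames where the
smoothed amplitude stays above `floor_frac` = 0.25 of its initial value,
i.e. the first two half-lives) is *mathematically the same region* as the
derivative-fraction rule at alpha = 0.25, evaluated on the model rather
than on a noisy numerical derivative — which is what makes it robust: in
the tail the log-noise diverges and a naive derivative extremum would lock
onto a noise spike. Recovery of the rate constant is exact on noiseless
data and within a few percent at realistic noise; condition comparisons
(the usual "x-fold quench" statement) are ratios of rate constants, which
are also invariant to the amplitude convention. The signed log-slope and
its positive magnitude `rate_per_s` are both reported.

`peak_amplitude()` is max(R/R0) after the event minus the baseline mean
(1 by construction); the global maximum is used when several transients
fall in a segment, and non-positive amplitudes are flagged rather than
silently returned.

## 4. TIRF puncta

`segment_puncta()` thresholds at median + k·MAD of the in-mask intensities
(default k = 5) — robust to the puncta themselves because they occupy only
a few percent of the footprint — groups suprathreshold pixels by
8-connected components (the labelling is implemented in the package;
connectivity is fixed so that counts are reproducible), removes components
under 4 px (shot-noise singletons), and reports per-punctum area in µm²
and coverage = total punctum area / footprint area, clipped at 1. Otsu's
threshold is available as an alternative. Raising the threshold can only
shrink the suprathreshold set, so coverage is monotone non-increasing in
k — a property the tests check directly.

One interaction deserves a warning: with a non-zero PSF, where the
threshold cuts the blurred edge profile determines the segmented area. A
k·MAD threshold sits just above the noise floor, far below the half-max
contour, so blurred puncta segment systematically larger than their true
area (the area is preserved only at the 50% contour of a symmetric blur).
The synthetic generator therefore renders crisp discs by default
(`psf_sigma_px = 0`), where segmented area differs from truth only by
pixel quantization; the blurred regime is exercised in a dedicated test
(counts and centroids are still recovered; area grows boundedly).

`line_profile()` samples co-registered channels along a line by bilinear
interpolation on an identical grid (so per-channel profiles are directly
comparable), averaging across an odd number of 1 px-spaced parallel lines.
Coordinates are (x = column, y = row), 1-based at pixel centres.

## 5. Group statistics and the pipeline

Group comparisons are one-way ANOVA with Tukey HSD (all pairs) or
Dunnett (versus a named control), delegated to `stats::aov()`,
`stats::TukeyHSD()` and `multcomp::glht()` — these are routine, well-tested
methods and reimplementing them would only add risk. Adjusted p-values map
to the four-level star convention (0.05/0.01/0.001/0.0001). Zero
within-group variance is flagged as degenerate rather than reported as an
impressive p-value. The suite verifies the family-wise error under a
three-group null by simulation (~5% at 1000 draws).

`run_pipeline()` chains morphometry, cortical filtering, summaries,
plateau estimation, kinetics and puncta segmentation, writing CSVs plus a
provenance JSON (resolved configuration, seed, config hash, versions).
Configuration keys are validated strictly — an unknown key is an error
naming the key — and outputs are byte-identical given the same
configuration and seed. On failure, partial outputs are removed.

## 6. The synthetic generators: what they emulate, and what they do not

All generators are pure functions of their seed (Mersenne-Twister /
inversion, recorded in the output metadata), and noiseless settings
produce inputs on which every estimator recovers its ground truth exactly;
this is what makes them usable as oracles.

* `simulate_trace_pair()` builds parallel lines or concentric arcs with
  optional per-vertex Gaussian jitter (default spacing 10 nm, jitter 1 nm
  when enabled — a careful hand trace). It does not model EM physics:
  staining variability, section compression, or membrane thickness.
* `simulate_cer_population()` draws log-normal lengths and a two-component
  gap law: short structures around 17 nm (broad), structures past the
  plateau onset around the tether's plateau gap, truncated to (0, 30] nm.
  It encodes the *pattern* the plateau estimator assumes, not a biophysical
  model of tethering.
* `simulate_fura2_recording()` builds the store-depletion/readmission
  protocol (default events: SERCA inhibition at 60 s, Ca2+ readmission at
  660 s, removal at 780 s; frame interval 0.5 s; R/R0 noise s.d. 0.005,
  matching visually clean averaged recordings) with an instantaneous-rise,
  exponential-decay release transient, a linear entry rise hard-clamped at
  the plateau (making "max derivative = entry slope" exact), exponential
  extrusion, and exponential 360 nm quench. Real transients rise with
  finite kinetics and real rises saturate smoothly; the generator
  deliberately prefers constructions whose ground truth is exact over
  biophysical realism, so recovery tests demonstrate estimator
  correctness, not robustness to model misspecification.
* `simulate_tirf_image()` renders non-overlapping discs of stated area in
  an elliptical (or supplied) footprint with Gaussian noise and optional
  PSF blur. It does not model photobleaching, TIRF penetration depth, or
  punctum substructure.

Passing tests on these inputs shows the estimators are correct under the
stated models and noise levels; it does not certify performance on
arbitrary real data, where segmentation contrast, trace quality and
protocol timing vary.

## 7. Numerical choices and problem sizes

Resampling keeps both polyline endpoints and never exceeds the requested
spacing. Degenerate inputs error early with specific messages: traces with
fewer than 2 points or zero extent, non-positive gaps/lengths/frame
intervals, events outside the recording, empty masks, zero-length profile
lines, segments shorter than 5 frames. Ties in the derivative extremum go
to the earliest frame. Truncated-normal draws use rejection sampling (the
degenerate s.d. = 0 case returns the mean, which must lie inside the
interval).

The test suite sizes its simulations for tight statistical checks at
interactive runtimes: 50-seed recovery loops for traces and recordings,
500-replicate bootstrap-coverage and 1000-replicate family-wise-error
simulations, 20-seed image recovery; the whole suite runs in roughly two
minutes.

## 8. Known limitations

* The gap estimator averages over the cER trace; for strongly re-entrant
  (self-folding) structures the nearest PM point may not be the
  biologically apposed one. Hand-traced inputs of single contact sites do
  not exhibit this.
* The cylinder cleft-volume model is a deliberate idealisation; its
  diameter convention is isolated in `cleft_volume()`.
* The plateau is a thresholded mean, not an asymptote fit; with few long
  structures the estimate inherits their noise (the bootstrap CI makes
  this visible).
* Decay-rate estimation assumes a single-exponential with a known
  asymptote; multi-exponential clearance would be mis-summarised by one
  rate.
* Puncta areas under PSF blur depend on the threshold rule (section 4);
  absolute coverage from blurred images should be interpreted with the
  threshold in mind.
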
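# mcsquant

Quantitative analysis of cortical-ER / plasma-membrane (ER-PM) contact
sites, for cell biologists studying store-operated Ca²⁺ entry (SOCE).

When ER Ca²⁺ stores empty, the cortical ER (cER) expands along the plasma
membrane and STIM-ORAI complexes assemble in the cleft between the two
membranes. Three kinds of measurements characterise this system, and
`mcsquant` implements all three as a tested, reproducible pipeline:

1. **EM morphometry of traced membranes.** From a pair of hand-traced
   polylines (PM and apposed cER membrane, in calibrated nm), the package
   computes the ER-PM **gap distance** *g* (the mean over resampled cER
   points of the minimum point-to-polyline distance to the PM), the **cER
   length** *L* (arc length of the long-axis trace), and the **cleft
   volume** modelled as a cylinder of diameter *L* and height *g*:

   *V* = π (*L*/2)² · *g*

   Structures are kept only if *g* < 30 nm (the defining criterion of
   "cortical" ER). Per-condition summaries (mean ± s.d.) and fold changes
   complete the analysis.

2. **Gap-versus-length plateau.** Long cER sheets anchored by tether
   proteins (E-Syts, MAPPERs) sit at a tether-specific gap. `plateau_gap()`
   formalises the dashed line of a gap-vs-length scatter plot as the mean
   gap of structures with *L* strictly above a threshold (300 nm by
   default), with sample s.d. and a seeded bootstrap 95% CI.

3. **Fura-2 kinetics and TIRF puncta.** `ratio_trace()` turns raw
   340/380/360 nm intensities into background-subtracted R/R0 traces;
   `slope_from_derivative()` implements derivative-guided linear-regression
   slope extraction (SOCE entry rates in R/R0 s⁻¹); `extrusion_rate()` and
   `quench_rate()` fit exponential decay constants (Ca²⁺ clearance, Mn²⁺
   quench of the isosbestic 360 nm signal); `segment_puncta()` and
   `line_profile()` quantify tether puncta (area, PM coverage) in TIRF
   images.

Every input type has a seeded synthetic generator
(`simulate_trace_pair()`, `simulate_cer_population()`,
`simulate_fura2_recording()`, `simulate_tirf_image()`) that attaches its
ground truth, so the whole pipeline is testable end-to-end without raw
microscopy data.

## Worked example

```r
library(mcsquant)
library(dplyr)

# three synthetic EM trace pairs with 1 nm tracing jitter
traces <- bind_rows(lapply(1:3, function(i)
  simulate_trace_pair(gap_nm = 17, length_nm = 60 + 10 * i, noise_sd_nm = 1,
                      structure_id = sprintf("S%02d", i), seed = i)))
cer_morphometry(traces)
#> # A tibble: 3 × 7
#>   structure_id condition tether gap_nm n_distance_samples length_nm
#> 1 S01          NT        none     16.5                143      70.6
#> 2 S02          NT        none     15.3                164      81.3
#> 3 S03          NT        none     17.4                183      90.8
```

The recovered gaps scatter around the true 17 nm and lengths around
70/80/90 nm; `n_distance_samples` counts the resampled cER points averaged
per structure (one per 0.5 nm pixel).

```r
pop <- simulate_cer_population(1000, plateau_gap_nm = 5.2, seed = 1)
plateau_gap(pop, length_threshold_nm = 300)
#> # A tibble: 1 × 9
#>   condition tether   length_threshold_nm n_long plateau_gap_nm sd_nm sem_nm
#> 1 CF        MAPPER-L                 300    246           5.14  1.23 0.0785
```

246 of the 1000 structures are longer than 300 nm; their mean gap, 5.14 nm
(s.e.m. 0.08), recovers the generating plateau of 5.2 nm.

```r
rec <- simulate_fura2_recording(n_rois = 3, seed = 1)   # entry slope 0.02 /s
entry_rate(ratio_trace(rec))
#> # A tibble: 3 × 9
#>   roi_id kind  direction slope_per_s r_squared t_start t_end n_points
#> 1 roi01  entry rising         0.0199     0.999    660.  685        50
#> 2 roi02  entry rising         0.0200     0.999    660.  684        48
#> 3 roi03  entry rising         0.0201     0.999    660.  684.       49

fold_change(66, 156, "length")
#> # A tibble: 1 × 5
#>   field  mean_from mean_to ratio label
#> 1 length        66     156  2.36 2.4-fold
```

Each ROI's SOCE entry slope is fitted over the regression window the first
derivative selects (here 660-685 s, the whole linear rise after Ca²⁺
readmission), recovering the simulated 0.02 R/R0 s⁻¹. The fold change of
mean cER length from 66 to 156 nm is 2.36.

`run_pipeline(pipeline_config(), out_dir, seed)` chains the stages and
writes structure/summary/plateau/kinetics/puncta CSVs plus a provenance
record; rerunning with the same config and seed reproduces the tables
byte-identically.

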
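# cordmotor

Analysis pipeline linking cervical spinal cord compression severity to
motor-network fMRI activation in degenerative cervical myelopathy (DCM).

DCM compresses the cervical cord and degrades hand and gait function.
The scientific question this package operationalizes: does a volumetric
measure of cord compression severity track how strongly — and how
extensively — the brain's motor network activates during a paced
finger-tapping task, and how do both relate to clinical disability
(mJOA, the 18-point modified Japanese Orthopaedic Association score)?

The pipeline has five computational stages, each exposed as ordinary R
functions and driven end-to-end by synthetic data with known ground
truth:

1. **Morphometry** — from a binary cord segmentation, the per-slice
   cross-sectional area profile a(z); compressed intervals are detected
   from the rate of change da/dz (a region opens where the negative
   slope exceeds a threshold fraction of the baseline area and closes
   where the recovering slope falls back below it), and summarized as
   the cord volume in the region, Σ a(z)·Δz, plus the volume deficit,
   Σ max(0, a₀ − a(z))·Δz.
2. **Reliability** — intraclass correlations of repeated rater
   measurements: inter-rater ICC(2,1) = (MS_S − MS_E)/(MS_S +
   (k−1)MS_E + k(MS_R − MS_E)/n) and intra-rater one-way ICC(1,1), with
   variance components reported.
3. **BOLD GLM** — block paradigm (11 × 30 s segments at TR 1 s, 330
   volumes) convolved with a double-gamma HRF, six motion nuisance
   regressors, voxelwise OLS; the task effect reported as % BOLD signal
   (100·β·range(x)/β₀) and as Z; cluster-based thresholding (Z > 3.1)
   with sign-flip permutation correction (Gaussian random-field
   approximation available).
4. **ROI metrics** — per-ROI % BOLD signal and volume of activation
   (VOA) for contralateral cortical (M1, S1, SMA, PMC) and bilateral
   subcortical (cerebellum, putamen, caudate, thalamus) regions.
5. **Association** — Pearson correlation battery (r, two-sided p,
   per-pair n, BH-adjusted column) between compression volume,
   activation metrics, mJOA and symptom duration, plus validation and
   summary statistics of the packaged 23-patient clinical table.

See `vignettes/cord-compression-fmri.Rmd` for the full model
description, parameter rationale and limitations.

## Worked example

Generate a compressed-cord phantom, measure it, and check rater
reliability of the measurement:

```r
library(cordmotor)

spec <- cord_phantom_spec(
  n_slices = 60,
  compressions = list(list(center_slice = 30, extent_slices = 7,
                           max_area_reduction = 0.5, shape = "box")))
ph <- make_cord_phantom(spec)
mm <- measure_compression(ph$mask)
mm$summary
#>   n_regions total_compression_volume_mm3 total_volume_deficit_mm3
#> 1         1                     159.4688                   154.35

ph$ground_truth[[1]]$deficit_mm3     # analytic truth: 0.5 * pi * 4^2 * 7 * 0.9
#> [1] 158.3363
```

The measured deficit (154.4 mm³) agrees with the analytic ground truth
(158.3 mm³) to 2.5% — the residual is disk digitization on the 0.25 mm
phantom grid — and the cord volume remaining in the 7-slice compressed
interval is 159.5 mm³. Simulated repeated measurements recover the
reliability structure:

```r
set.seed(1)
rt <- make_rater_table(rnorm(23, 1500, 400), n_raters = 2, n_repeats = 3,
                       rater_bias_sd = 15, residual_sd = 40, seed = 2)
icc_inter(rt)
#> <icc_result> ICC = 0.996 (two-way-random-absolute-single), 23 subjects, 46 ratings
#>   variance components: subject 1.231e+05, rater 0, residual 521.5
icc_intra(rt, "rater1")
#> <icc_result> ICC = 0.984 (one-way-random-single), 23 subjects, 69 ratings
```

A full synthetic study — cord phantoms and BOLD runs whose activation
tracks a latent severity, GLM, ROI extraction, correlation battery —
runs in under a minute:

```r
run_pipeline(pipeline_config("out", seed = 23, n_subjects = 23))
```

which in `out/association/battery.csv` recovers the seeded
compression–activation relationship (contralateral M1 % BOLD:
r = 0.64, p = 0.001, n = 23 for that seed). The numbered scripts under
`analysis/` walk through each stage the same way and write their tables
under `results/`.

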
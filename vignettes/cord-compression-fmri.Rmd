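---
title: "Quantifying cervical cord compression and its motor-network fMRI correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cervical cord compression and its motor-network fMRI correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmotor)
```

## The analysis problem

Degenerative cervical myelopathy (DCM) narrows the cervical spinal canal
and compresses the cord. Two questions drive the analysis this package
implements: how severely is a given cord compressed, expressed as a
single volumetric number per patient, and does that severity relate to
how strongly the brain's motor network activates when the patient
performs a paced finger-tapping task. The pipeline therefore has three
scientific layers — cord morphometry, per-subject task-fMRI statistics,
and cohort-level correlation against the modified Japanese Orthopaedic
Association (mJOA) disability score — plus a reliability layer for the
morphometric measurement and a synthetic-data layer that makes every
stage testable with known ground truth.

Patient imaging for studies of this kind is typically available only on
request, so nothing here depends on real acquisitions: phantom
generators produce cord masks with analytically known compressions, BOLD
runs with known percent signal change, rater tables with known variance
components, and cohorts with known correlation structure. The one piece
of real data shipped with the package is the transcribed 23-patient
demographic and clinical table (`load_cohort_table()`), which anchors
the cohort-summary and validation code.

## Cord compression morphometry

The measurement starts from a binary cord segmentation (a `cord_mask`)
and reduces it to a one-dimensional profile: the cross-sectional area of
each axial slice, inferior to superior, computed as voxel count times
in-plane voxel area (`compute_area_profile()`). A focal compression is a
localized dip in this profile. Its limits are found from the rate of
change of area (`detect_compression()`):

* central differences of the (optionally moving-average smoothed)
  profile are scanned;
* a candidate region opens where the negative slope exceeds
  `slope_threshold` × baseline area per slice, and closes where the
  recovering positive slope falls back below that threshold;
* the reported limits are the slices of steepest descent and steepest
  ascent, which on box-shaped dips coincide exactly with the true edges;
* the baseline area is the median of slices outside detected regions,
  estimated iteratively (global median first, one refinement pass), so
  the compression does not drag its own baseline down.

Two volume metrics are computed per region (`compression_volume()`).
`cord_volume_in_region` — the sum of slice areas inside the region times
slice thickness — is the headline "total compression volume", the shaded
area under the profile. `volume_deficit` — the summed shortfall relative
to the baseline area — is always emitted alongside, because "volume of
the compressed region" admits both readings and the deficit is the more
directly interpretable severity number. When several regions are
detected the subject-level totals sum across regions; clinically a
single site is typical, so the sum is an extension, not a requirement.
Slice limits are 1-based and inclusive throughout, and an empty slice
inside a region contributes zero area, i.e. maximal deficit —
conservative handling of segmentation dropout.

### Parameter defaults and why

* `window = 3` slices of moving-average smoothing stabilizes the
  derivative without displacing box edges by more than one slice.
* `slope_threshold = 0.05` (5% of baseline area per slice): compressions
  of clinical interest reduce area by 20% or more over a few slices, so
  their edge slopes are several times this value, while the profile of a
  healthy cord varies much more slowly.
* `min_extent = 3` slices (2.7 mm at 0.9 mm slices) discards
  single-slice artefacts.
* `min_depth = 0.15`: a detected region must actually dip below 85% of
  the baseline area. The slope rule alone turns out to be insufficient
  at realistic segmentation surface noise — with 0.2 mm radius noise the
  per-slice slope noise is of the same order as the threshold, and pairs
  of chance crossings would otherwise assemble into spurious shallow
  "regions". The depth criterion prunes these while keeping every
  compression of 20%+ area reduction detectable (a 20% box compression
  of three or more slices always retains at least one slice at full
  depth after window-3 smoothing).

All four are explicit arguments and are recorded in each region's
`detection_params`, because the original description of the method fixes
none of them.

### Phantoms and digitization

Cord phantoms are stacks of digital disks rasterized by centre-of-voxel
inclusion (x² + y² ≤ r²), with compressions applied to *area* rather
than radius so the ground-truth deficit is analytic (for a box:
reduction × πr₀² × extent × thickness). The default phantom grid is
0.25 mm in-plane with 0.9 mm slices: the slice thickness of a typical
T2-weighted spine acquisition, and an in-plane grid fine enough that the
lattice-count error of a digital disk stays a few percent of even the
smallest (20%) deficit of interest. On coarse grids digitization noise
alone can reach tens of percent of a shallow deficit, which would say
nothing about the detector. The tests sweep box compressions of 3–15
slices and 0.2–0.6 area reduction and require limits within one slice
and deficits within 5% of the analytic truth; robustness is checked at
0.2 mm surface noise, where the deficit's coefficient of variation
across seeds stays below 10% — the synthetic mirror of the high
test-retest reliability the measurement is designed for.

Gaussian-shaped compressions are also supported; their ground-truth
interval is defined by the profile's inflection points (centre ± σ,
where the slope rule's extrema sit on the continuous profile), and their
full analytic deficit integrates the whole bell, so the region-restricted
deficit is expected to undershoot it. The oracle-equivalence sweeps
therefore use box shapes.

## Rater reliability

The measurement's reliability is quantified with intraclass correlations
computed from ANOVA mean squares, with the model made explicit because
"the ICC" is ambiguous:

* `icc_inter()` — ICC(2,1), two-way random effects, absolute agreement,
  single measurement: (MS_S − MS_E) / (MS_S + (k−1)MS_E + k(MS_R −
  MS_E)/n). Raters are modelled as random and absolute agreement is the
  clinically relevant question when two specific people measure the same
  volumes. Repeats are averaged within rater first by default, matching
  a three-repeats-per-rater design.
* `icc_intra()` — ICC(1,1), one-way random effects over a single rater's
  repeats: (MS_B − MS_W) / (MS_B + (k−1)MS_W).

Variance components and the model label ride along in every result so
the choice is auditable. Balanced designs are required and missing cells
are listed on error; negative estimates are reported as computed, with a
flag, rather than truncated — truncation would hide degenerate designs.
The estimator is verified against an independent `aov()` mean-squares
oracle, against the closed form σ²_b/(σ²_b + σ²_e) on large one-way
simulations, and for parameter recovery at the study's design size
(23 subjects, 3 repeats) across true ICCs of 0.5/0.8/0.95, where the
mean estimate must sit within the analytic large-sample sampling SD
√2(1−ρ)(1+(k−1)ρ)/√(k(k−1)(n−1)).

## Block-design BOLD GLM

The task paradigm is 11 alternating segments of 30 s starting at rest —
six rest, five active — at TR 1 s, i.e. 330 volumes, with pacing cues
every 3 s carried as metadata (the block, not the cues, is modelled).
The task regressor is the boxcar convolved with a double-gamma
haemodynamic response (positive lobe mean 6 s, undershoot mean 16 s,
undershoot ratio 1/6 — the canonical convention, all configurable),
truncated to run length and scaled to unit peak-to-baseline range.

That scaling is the percent-signal convention: `fit_glm()` reports
percent signal as 100 × β_task × range(task regressor) / β_intercept.
Because the BOLD phantom modulates its baseline with exactly the same
unit-range regressor, a noiseless phantom closes the loop to machine
precision (the tests require 2.00% recovered to 1e-6), and the quantity
is comparable across voxels since each voxel is normalized by its own
baseline.

Other statistical choices:

* Ordinary least squares per voxel with the six motion parameters
  (three translations, three rotations) and an intercept as nuisance
  columns; rank deficiency is rejected naming the collinear columns.
* t statistics are mapped to Z through the two-sided t-CDF / normal
  quantile transform at nominal residual degrees of freedom. On null
  phantoms the z field is empirically standard normal
  (Kolmogorov–Smirnov check at ~10⁴ voxels).
* Temporal autocorrelation is *not* modelled. The phantom noise is
  white, so all calibration tests are exact under the package's own
  simulator; on real data, nominal degrees of freedom would be
  optimistic and prewhitening would be required. This is a documented
  deviation, not an oversight.
* Spatial smoothing (`smooth_volume()`) converts FWHM in mm to a
  per-axis Gaussian sigma and convolves separably with reflective
  boundaries; the default mode smooths each axial slice in 2-D,
  matching the acquisition-style per-slice description, with a 3-D mode
  available.

### Cluster-based thresholding

Suprathreshold voxels (default Z > 3.1) are grouped by 26-connectivity
(configurable to 6). Cluster-level corrected p-values come from one of
two methods:

* **Sign-flip permutation (default).** Residuals about the reduced
  (nuisance-only) model are sign-flipped per volume, added back, the
  full model refitted, and the maximum suprathreshold cluster size
  recorded; a cluster's corrected p is the fraction of null maxima at
  least as large, with the +1 correction. This is exact at phantom scale
  under symmetric errors, needs no smoothness estimation, and its
  family-wise error is verified over 200 null simulations.
* **Gaussian random-field approximation.** The stationary
  expected-cluster formulation with smoothness estimated from
  normalized residual gradients, provided for comparability with
  conventional fMRI tooling and flagged approximate — small discrete
  phantoms violate its assumptions.

Whether a published "Z > 3.1, P = 0.001" refers to the cluster-forming
threshold or the cluster-level alpha is genuinely ambiguous; both are
independent arguments here (`z_threshold`, `alpha`) and the tests
exercise the pair explicitly rather than resolving the ambiguity.

## ROI metrics

`extract_all()` computes, per region of interest, the two activation
summaries the cohort analysis consumes: percent BOLD signal — the mean
percent-signal over the ROI's suprathreshold voxels — and the volume of
activation (VOA), the suprathreshold voxel count inside the ROI times
voxel volume. Cortical ROIs (M1, S1, SMA, PMC) are read from the
hemisphere contralateral to the tapping hand; subcortical ROIs
(cerebellum, putamen, caudate, thalamus) are bilateral. Whether
published percent-BOLD values average suprathreshold voxels or the whole
ROI is unstated in this literature; the suprathreshold mean is the
default and the whole-ROI mean is always emitted alongside. An ROI with
no suprathreshold voxels yields 0 with an `empty-intersection` flag
rather than a missing value — the cohort correlation needs one value per
patient, and 0 encodes "no significant activation", flagged for audit.
Probabilistic atlas maps are thresholded at 25% by default (a common
atlas convention, configurable) with nearest-neighbour resampling onto
the statistic grid; atlases are inputs, not bundled, and the test
surface uses synthetic ROI sets.

## Cohort association

`correlation_battery()` computes Pearson correlations over
pairwise-complete cases with the per-pair n reported, p-values two-sided
from t = r√((n−2)/(1−r²)). No multiplicity correction is applied to the
reported p-values — matching how per-pair brain–behaviour correlations
are conventionally reported in this literature — but a
Benjamini–Hochberg column is emitted alongside for the reader's own
judgement. Degenerate pairs (constant variable, n < 3) stay in the
output flagged rather than erroring, so the battery's shape is
predictable. Display convention: r to two decimals, p to two significant
figures, with full precision retained.

The cohort generator draws a multivariate Gaussian with a target
correlation matrix (validated positive semi-definite), maps each
variable to its marginal mean and SD, and rounds/clips mJOA-named
variables to the 0–18 integer scale. Simulation oracles verify that at
the study size (n = 23) the sample correlation is unbiased for a true
ρ = 0.56 within 0.05 over 500 cohorts, that null rejections at α = 0.05
occur at 5% within binomial error, and that empirical power matches the
Fisher-z approximation Φ(√(n−3)·atanh ρ − z₀.₉₇₅) within five points.

## What the synthetic data does and does not emulate

The generators reproduce the *geometry and statistics* the pipeline is
sensitive to: localized area reductions of known volume, block-design
signal of known amplitude with white Gaussian noise and smooth motion
traces, rater tables with specified variance components, cohorts with
specified correlation structure. They deliberately do not model scanner
physics: no physiological or autocorrelated noise, no spikes or
distortion, no anatomically realistic brain or cord, no segmentation
errors beyond surface roughness. Passing tests therefore demonstrate
correctness of the estimators under their stated assumptions, not
robustness to everything real acquisitions do; the autocorrelation
caveat above is the largest gap for real BOLD data.

All generators are bit-reproducible: one seed per call, with named
deterministic sub-streams, and the RNG state of the calling session is
never disturbed.

## Problem sizes and runtime choices

Simulation-heavy checks use deliberately compact configurations chosen
to estimate each property to the precision its tolerance needs: null-z
calibration on a ~10⁴-voxel grid with the full 330-volume paradigm;
family-wise-error calibration over 200 null runs of 12 × 12 × 8 voxels
with an 11 × 10 s paradigm and 150 sign-flip permutations each; ICC
recovery over 200 replicates per true value; correlation recovery over
500 cohorts. The end-to-end demonstration (`analysis/06_pipeline_demo.R`)
runs 23 synthetic subjects through every stage in well under a minute.

## Known limitations

* No vertebral-level labelling: sites of impairment (C3-4 … C6-7) are
  clinical inputs, not derived from the image.
* No cord segmentation; masks are assumed given and binary.
* No prewhitening or group-level inference in the GLM; the analysis is
  per-subject, as the cohort design requires.
* The random-field correction is an approximation at phantom scale;
  the permutation route is the calibrated default.
* `pearson_association()` assumes bivariate normality for its p-values;
  ranks or permutation alternatives are out of scope because the cohort
  analysis is defined in terms of Pearson's r.
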
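---
title: "Dissociating input modality from amodal semantic coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating input modality from amodal semantic coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubspoke)
```

## The scientific question

The hub-and-spoke account of semantic memory holds that word meaning is
represented twice over: in modality-specific sensory "spoke" regions, and in
an amodal "hub" in the ventral anterior temporal lobe (ATL) that integrates
across input channels.  A critical prediction is a dissociation *within* the
ATL: superior regions (aSTG) should carry information about how a word was
presented (spoken vs written), while ventral regions should carry
information about what the word means (e.g. whether it denotes an auditory
feature like *loud* or a visual feature like *shiny*) regardless of
presentation format.

`hubspoke` implements the full analysis chain needed to test that
prediction — block-design GLM feature extraction, cross-modal searchlight
classification, permutation group inference, a region-by-classifier
dissociation ANOVA, seed-based resting-state connectivity with CompCor
nuisance correction, template-network overlap, and meta-analytic
spatial-correlation decoding — together with a synthetic BOLD phantom whose
generative ground truth embodies the hypothesis, so every stage can be
validated by recovery rather than by fiat.

## The phantom

`make_phantom_atlas()` builds a deterministic region atlas on a 28^3 grid of
2 mm voxels (the grid spacing of the analyses; full-brain grids are
supported but not the default): a spherical "brain" containing a
semantic-hub region (150 voxels), a modality region (150), auditory and
visual spokes (80 each), plus white-matter (200) and CSF (100) compartments
outside the gray mask.  Region sizes were chosen to be comparable to the
searchlight sphere (123 voxels at 6 mm radius on this grid) so that
recovery is neither trivial nor hopeless; they are configuration, not
magic.

`phantom_truth()` plants the hypothesis as multivoxel structure.  Each
region receives fixed zero-mean, unit-norm pattern vectors drawn once per
subject:

* the **hub** has one pattern per semantic feature class (AUD, VIS),
  identical for spoken and written presentation, and no response to
  non-words (meaningless items carry no meaning to encode);
* the **modality region** has one pattern per presentation format,
  identical across AUD/VIS/NON content;
* each **spoke** carries both a format and a feature pattern (summed and
  renormalised for word conditions).

The task simulator (`simulate_task_subject()`) generates a 4-run session:
each run holds 12 blocks — two per condition in a pseudo-random order with
no immediate repetition, built by rejection sampling — separated by rest
gaps drawn uniformly from 4–8 s.  Blocks last 20 s, giving runs of roughly
160 volumes at TR = 2 s.  The voxel signal is

    baseline + sum_c amplitude * pattern_c(voxel) * x_c(t) + drift + AR(1) noise

where `x_c` is the condition boxcar convolved with the double-gamma
haemodynamic response and scaled to unit peak.  Defaults: baseline 100
(so amplitudes read as percent signal change), amplitude 2 %, white noise
sd 1, AR(1) coefficient 0.3, peak-to-peak linear drift 2.  These place
single-subject searchlight accuracies in the 0.6–0.8 range, matching the
regime where group inference is informative rather than saturated.
Motion parameters are simulated as smooth random walks and used only as
confound regressors; motion *correction* is out of scope, as the phantom is
generated pre-aligned.  One catch item per block in the original task
design does not enter the condition model and is not simulated.

The rest simulator (`simulate_rest_subject()`) produces 180 volumes at
TR = 3 s: two independent latent network time courses, band-limited to
0.01–0.08 Hz (an assumption — the generator does not model how the
preprocessing low-pass interacts with network frequency content), with
disjoint high-loading territories anchored at the modality region +
auditory spoke (network 1) and the hub + visual spoke (network 2); a
physiological confound (0.01–0.15 Hz) loading at 1 on WM/CSF and 0.4 on
gray matter; and white noise (sd 1).

Both simulators accept an `roi` argument that restricts synthesis to the
bounding box of an analysis mask.  This is purely computational: the
signal and noise law of every retained voxel is identical to the full-grid
run (verified bit-exactly for the noiseless signal in the test suite),
only the particular noise draws differ.

### What the phantom does *not* emulate

No k-space physics, susceptibility dropout, slice timing, or motion
artefacts; noise is stationary AR(1) rather than physiologically
structured; regions are compact balls rather than cortical sheets.
Passing recovery tests therefore demonstrates that the *analysis chain* is
correct and calibrated under its own assumptions — not that it is robust
to every artefact of real acquisitions.

## GLM feature extraction

`build_design_matrix()` convolves condition boxcars with the double-gamma
HRF at a microtime resolution of 16 samples per TR and downsamples to scan
onsets.  Two conventions deserve note:

* **HRF parameterisation.**  Each gamma lobe uses shape
  `delay / dispersion + 1` and scale `dispersion`, so the positive lobe's
  mode falls exactly at `peak_delay` (default 6 s) and the undershoot's at
  16 s, with relative amplitude 1/6 and 32 s support.  The kernel is
  scaled to unit peak.
* **Unit-peak regressors.**  Each task regressor is rescaled to maximum 1
  after convolution, so a fitted beta is the peak response in signal units
  and `percent_signal_change()` (100 × beta × max(regressor) / intercept)
  returns the planted amplitude exactly on a noiseless phantom.  The
  scaling convention is recorded here because percent-signal-change
  formulas differ across packages.

High-pass filtering is a cosine (DCT) drift basis with all half-periods
above 1/cutoff (default 0.01 Hz) added to the confounds — the standard
re-implementable equivalent of a Gaussian-weighted running-line detrend.
Fitting is voxelwise OLS via QR; no autocorrelation prewhitening is
applied (AR noise is absorbed by the subject-level variance that the
permutation group level respects).  Condition regressors are fit jointly
with the drift basis, not orthogonalised against it beforehand.
Fixed-effects combination across runs is the unweighted beta mean; with
equal-length, identically structured runs this coincides with the
variance-weighted version and is exactly testable.

`tsnr_map()` divides the voxel's mean raw signal by the standard deviation
of its GLM residuals; voxels with zero residual variance are undefined and
excluded from summaries (mean and fraction above 20).

## Cross-modal MVPA

Features are per-run, per-condition beta maps, z-scored per voxel within
each run across all six condition maps (regardless of which scheme is then
run).  Two classification schemes implement the dissociation logic:

* **semantic_feature** — decode AUD vs VIS words, trained on spoken and
  tested on written items *and vice versa*, the two directions averaged.
  Only meaning shared across formats can drive accuracy.
* **perceptual** — decode spoken vs written, trained on non-words and
  tested on the four word conditions pooled by format.  Only format
  information generalising from meaningless to meaningful items counts.

Cross-validation is leave-one-run-out: for each direction and fold the
classifier trains on the direction's train conditions from the three
training runs (3 samples per class) and tests on its test conditions from
the held-out run only; all fold × direction accuracies are averaged
(semantic: 8 evaluations, perceptual: 4).  This is the strictest join of
"train on three runs, test on the fourth" with the cross-modal train/test
split; restricting test samples to the held-out run is a deliberate choice
— testing on all runs would not leak (train and test conditions are
disjoint) but would blur the fold semantics.

The classifier is a soft-margin linear SVM with C = 1, solved by an
in-package SMO (sequential minimal optimisation) routine in C++ with
maximal-violating-pair working-set selection and a 1e-8 duality-gap
tolerance.  The test suite verifies it against two independent references:
a brute-force active-set enumeration of the dual QP on 4-point problems
(to 1e-4, with the bias checked against its KKT-feasible interval when no
free support vectors pin it), and LIBSVM via e1071 on random 8-sample
problems (to LIBSVM's own 1e-3 termination tolerance).  A decision value
of exactly zero predicts the alphabetically first class and is flagged;
with continuous features its probability is nil.

The searchlight evaluates this cross-decoding in 6 mm-radius spheres (123
voxels on the 2 mm grid — enumeration confirms the count; on a 3 mm grid
it is 33) centred at every voxel of the analysis mask, clipped to the
mask, with centres whose clipped sphere holds fewer than `min_voxels = 2`
voxels marked invalid.  Accuracy maps are smoothed with a 6 mm FWHM
Gaussian using validity-aware renormalised convolution: invalid voxels
neither contribute weight nor receive values, which keeps ROI-restricted
maps unbiased at their borders.

## Group inference

`group_chance_test()` computes a voxelwise one-sample t of
(accuracy − 0.5) across subjects, converts it to z, forms clusters at
z ≥ 2.3 with 26-connectivity, and assigns family-wise-error corrected
p-values from a sign-flipping permutation null of the maximum cluster
mass (sum of z within a cluster).  Sign-flipping replaces the original
parametric mixed-effects machinery, which is not re-implementable
bit-exactly; nominal error levels are preserved by construction and
verified empirically (see below).  The same machinery serves the
resting-state seed contrasts at chance 0 — one implementation, tested
once.  Corrected p-values are floored at 1/(n_perm + 1); fewer than 100
permutations records a warning in the result parameters.  Both the
corrected threshold (default 0.05) and the cluster-forming z are exposed
as parameters, since reported thresholds for such analyses vary (0.05 vs
0.01).

`dissociation_anova()` is the 2×2 within-subject ANOVA (region ×
classifier) on ROI-mean accuracies, each F on (1, n−1) degrees of
freedom, with paired t-tests for the two simple effects of region within
each classifier.  Zero error variance is reported as an undefined F with
a note rather than an arbitrary number.

## Resting-state connectivity

Seeds are spheres of 3 mm radius (the 6 mm *diameter* convention of the
connectivity analysis; the univariate percent-signal-change ROIs use 6 mm
*radius* spheres — the discrepancy between the two conventions is
preserved deliberately, both exposed as explicit radii).  CompCor extracts
the top five principal-component time courses of the variance-normalised
WM + CSF voxel time series; these plus the six motion parameters (11
nuisance regressors in total) are removed by OLS, after which Gaussian
temporal band filtering is applied (high-pass as the residual from a
100 s-sigma running Gaussian mean, low-pass with 2.8 s sigma).  Per-voxel
variance normalisation before the PCA follows the original CompCor
formulation; the seed time course is extracted *after* cleaning (the
alternative order is unstated in the source methods; this choice is
recorded here).  No global signal regression is performed.  Seed maps are
Fisher-z transformed Pearson correlations with the mean seed time course;
|r| above 0.999999 (the seed interior) is capped and flagged.
WM/CSF segmentation itself is out of scope: the phantom provides
ground-truth compartment masks and real-data users supply their own.

`network_overlap()` reports, for each binary template network, the number
of overlapping voxels and the proportion of the input map they cover.

## Meta-analytic decoding

`spatial_term_decode()` correlates an unthresholded statistic map with
every map of a term set over their jointly valid voxels (a brain mask is
optional and recorded; whether the original analysis masked is unstated)
and returns the 15 most positively and 15 most negatively correlated
terms, ties broken by term name.  The real meta-analytic database
(~11,000 term maps) is not shipped; `synthetic_term_maps()` generates
orthogonalised smooth random maps so the decoder's ranking behaviour is
testable — the synthetic stand-in is labelled as such everywhere.

## Calibration and recovery results computed by the test suite

The acceptance tests (`tests/testthat/test-acceptance.R`) compute, and the
package claims nothing beyond:

* sphere counts by brute-force enumeration (123 / 33);
* the exact fold ledger (8 and 4 evaluations);
* on 200 label-independent phantom sessions, the mean sphere accuracy lies
  within 3 standard errors of 0.5, and 200 null 12-subject cohorts put the
  group test's empirical FWE within Monte-Carlo slack of 0.05 (cohorts are
  drawn without replacement from the 200 null maps, so cohort outcomes
  share maps — an approximation accepted for runtime);
* noiseless betas invert the forward model to 1e-8 and OLS matches the
  normal equations to 1e-10;
* the planted dissociation (semantic cluster confined to the hub ROI,
  perceptual cluster to the modality ROI, significant interaction with
  both simple effects in the planted directions) is recovered in at least
  90% of 20 seeded 12-subject cohorts;
* seed contrasts recover at least half of each network's exclusive
  territory at corrected p < .05 in at least 90% of 10 seeded cohorts, and
  CompCor reduces off-network |z| in a paired comparison over those seeds;
* the generative term ranks first among 50 synthetic terms in at least
  95% of 100 decoding problems.

`scripts/acceptance.R` re-runs the null-calibration study from scratch at
an arbitrary seed and writes the mean null accuracy (in percent) as JSON.

Problem sizes in the suite (dataset counts, cohort sizes, 199
permutations per group test) were chosen as the smallest sizes at which
the binomial/Monte-Carlo error bands in the criteria are meaningful; they
are stated in each test.

## Numerical choices and degenerate inputs

* Zero-variance voxels: z-scoring sets them to 0 and flags them; tSNR
  reports them as undefined; seed maps mark them invalid.
* Rank-deficient designs fail loudly with the collinear columns named;
  collinear *confounds* in the connectivity cleaning are dropped with a
  recorded warning instead, since nuisance sets are routinely redundant.
* SVM ties (decision value exactly 0) go to the alphabetically first
  class, deterministically, and are flagged.
* All randomness flows from explicit integer seeds through a per-stage
  seed derivation (`master -> hash(stage label)`), so every result object
  is bit-reproducible; R's global RNG state is saved and restored around
  each seeded block.
* Cluster connectivity is 26-neighbour; cluster mass (not extent) is the
  permutation statistic.

## Known limitations

Real-data preprocessing (registration, motion correction, distortion,
segmentation) is out of scope; inputs are assumed pre-aligned NIfTI-1
volumes on axis-aligned grids.  The phantom's noise model understates
physiological structure in task runs (the shared physiological confound
exists only in the rest model).  The FWE calibration shares null maps
across cohorts as noted above.  The dissociation ANOVA assumes a complete
crossed design and will not pool over missing cells.
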
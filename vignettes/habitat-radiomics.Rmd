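---
title: "Habitat radiomics: models, choices and validation on phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics: models, choices and validation on phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Solid tumours are spatially heterogeneous: perfusion, cellularity and
necrosis vary across sub-regions ("habitats"), and the biology that drives a
clinical endpoint may live in one compartment rather than in the tumour as a
whole. Habitat radiomics operationalises this idea on a single
contrast-enhanced T1-weighted MR volume per patient: tumour voxels are
clustered into a small number of habitats from two per-voxel features —
grayscale intensity and slice-wise local entropy — and radiomics features
are then extracted separately from each habitat and from the whole tumour,
feeding identical feature-selection and classification pipelines whose
performance can be compared. The endpoint this package is built around is
the preoperative prediction of lymphovascular space invasion (LVSI) in
cervical cancer, a binary pathology-confirmed label.

`habitomics` implements that pipeline end to end, together with a synthetic
phantom generator with known habitat ground truth, so that every stage —
clustering, k-selection, extraction, selection, modelling, evaluation — can
be validated quantitatively on data where the right answer is known.

## Pipeline model, stage by stage

**Geometry and grayscale standardisation.** Images and masks are resampled
to 1 x 1 x 3 mm (cubic convolution for the image, nearest neighbour for the
mask) and intensities are min-max normalised to 0-255 over the VOI voxels
only. VOI scope makes habitat intensities comparable across patients; the
choice is recorded in the configuration. Min-max normalisation has a
consequence worth stating: any change that moves the VOI extremes rescales
every voxel, so the normalised scale is only as stable as the darkest and
brightest compartments.

**Voxel features.** Each voxel contributes its intensity and the Shannon
entropy (bits) of the `n_bins = 32` equal-width histogram of its in-plane
5 x 5 window, clipped at image borders, computed per slice. The entropy
stabiliser is placed inside the logarithm, `H = -sum p_i log2(p_i + eps)`
with `eps = 1e-12`: this keeps empty bins finite and converges to the
Shannon entropy as `eps -> 0` (placing `eps` outside the sum would leave
`log2(0)` undefined). Bin edges default to the volume's data range, which
makes the map invariant to adding a constant to the image. Whether a
sliding window or the whole slice is used is exposed in the configuration
(`window_radius`); windows are the default because whole-slice histograms
would assign every voxel of a slice the same value and carry no local
texture.

**Habitat clustering.** Both features are z-scored with parameters pooled
over the training cohort, so Euclidean distance is scale-free and test
patients reuse the stored transform. The number of habitats is selected at
the cohort level by consensus clustering over voxels pooled across training
patients (up to 2000 per patient, 5000 total by default): for each
candidate k in 2..10, voxels are subsampled at 80% and clustered 1000 times
(k-means++, Lloyd), and the consensus of a voxel pair is the fraction of
co-samplings in which it was co-clustered. Segmentation then runs per
patient at the chosen k*, and clusters are relabelled so the habitat index
increases with mean raw intensity — a deterministic rule that makes
"habitat h" comparable across patients.

**Choosing k.** The classical summary is the area under the consensus CDF
and its relative gain per k ("delta area"), with the optimum read off where
the gain collapses. We compute and report that curve, but the default
decision rule is PAC — the proportion of ambiguous clustering, the CDF mass
in (0.1, 0.9) — with k* the last candidate of the first contiguous run
whose PAC is at or below 0.1 (restricting to the first run matters: at
very large k most voxel pairs are never co-clustered at all, consensus
piles up near zero, and PAC can dip back under the threshold spuriously).
The reason for preferring PAC over a delta-area cutoff is structural: the
delta-area decays mechanically with k even for perfectly separated
clusters — under ideal balanced structure the area is 1 - 1/k, so the
relative gain at k is about 1/(k(k-2)) — which means the threshold that
recovers a small true k over-shoots a larger one and vice versa, and no
single value works across cases. PAC instead stays near zero for every k
up to the true structure and jumps as soon as clusters are split
inconsistently, which is what the k-recovery tests exercise. Both rules
are available
(`rule = "pac"` or `"delta"`); a single k-means start per replicate is
used deliberately, because extra restarts stabilise the splitting of true
clusters and blur the PAC signature.

**Radiomics extraction.** A native IBSI-style engine computes 18
first-order, 14 shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 14 GLDM
features, on the original image and optionally on 8 single-level
undecimated Haar wavelet sub-bands and Laplacian-of-Gaussian responses at
1, 2 and 3 mm. Texture discretisation is fixed bin width (default 25 on
the 0-255 scale), anchored at the region minimum, which makes texture
features invariant to intensity offsets. GLCM/GLRLM aggregate 13 3D
directions at distance 1 by averaging feature values. Shape surface area
uses a Crofton-corrected boundary-face estimator (exposed face areas
scaled by 2/3), which converges to the true area for smooth bodies where
a raw face count overestimates by about 3/2 — with the raw count, the
sphericity of a digitised sphere would plateau near 0.66 instead of 1.
Regions below 10 voxels are skipped and recorded. The published
feature-count of a particular extractor configuration is not a target;
counts are reported per run.

**Feature selection.** Four nested stages: (1) reproducibility — features
with inter-reader ICC below 0.75 are removed, using ICC(2,1), the two-way
random-effects absolute-agreement single-measurement form that is the
common radiomics choice for two readers; undefined ICCs (zero
between-subject variance) fail the screen. The wording "ICC < 0.75 were
retained" that circulates in clinical text is read as "ICC >= 0.75 were
retained", the only direction consistent with the screen reducing feature
counts. (2) z-scoring fitted on the training cohort only. (3) greedy
Pearson pruning at |r| > 0.9, visiting columns by descending raw variance
(ties by name) so the choice of survivor is deterministic and favours
informative features. (4) LASSO logistic regression, with lambda chosen to
minimise cross-validated binomial deviance over seeded stratified
five-fold assignments (minimum rule, not 1-SE).

**Modelling and evaluation.** One RBF-kernel SVM per region, with C in
{0.1, 1, 10, 100} and gamma at the 1/p scale heuristic times {0.1, 1, 10},
chosen by mean five-fold cross-validated AUC on shared seeded stratified
folds (decision values are used during the grid search — they rank
identically to Platt probabilities — and Platt scaling is fitted on the
final refit). The operating threshold is the Youden optimum of the
training ROC, applied unchanged to the test cohort. Evaluation reports
AUC with DeLong 95% CI, paired DeLong tests against the whole-tumour
reference (identical score vectors return p = 1 by convention), threshold
metrics, decile calibration with a logistic recalibration slope, and
decision-curve net benefit `NB(t) = TP/n - FP/n * t/(1-t)` against
treat-all and treat-none.

**Clinical statistics.** The characteristics battery uses the
Yates-corrected chi-square for 2 x 2 tables and the uncorrected Pearson
chi-square for r x c tables — the combination that reproduces the
published two-centre cervical-cancer table to its printed decimals — plus
Fisher's exact test (recommended automatically when any expected count
falls below 5), pooled-variance t (Welch by flag, summary-statistics input
supported so printed tables can be re-tested exactly), Mann-Whitney U,
and exact pooled stage-wise positivity proportions.

## What the phantom generator emulates

Each phantom is an ellipsoidal tumour on a 36 x 36 x 12 grid at
1 x 1 x 3 mm (a 30 mm tumour, matching the reported size range of the
clinical cohort), partitioned into concentric shells — core, intermediate,
rim — mimicking the radial perfusion structure of contrast-enhanced
tumours; an angular-sector geometry is available behind a flag. Habitats
differ in mean intensity (50 / 125 / 200, adjacent means three nominal
noise SDs apart at SD 25) and in texture via per-habitat Gaussian
smoothing of the noise field (2.5 / 1.2 / 0.4 mm, entropy decreasing from
rim to core). By default smoothing also damps the voxel SD, as a filtered
acquisition would; setting `preserve_noise_sd = TRUE` rescales the field
so smoothness controls only the spatial correlation length. A second
reader is emulated by a seeded sequence of one-voxel dilations/erosions of
boundary patches, bounded so that a 1 mm jitter keeps Dice above 0.9 on a
30 mm tumour.

Cohorts add between-patient variation: habitat-mean jitter, log-smoothness
jitter, and composition jitter (volume fractions re-normalised after
perturbation) — tumours differ in how much of each compartment they carry.
Labels are Bernoulli draws at the configured prevalence.

**Where the label signal lives, and why.** Label-positive patients receive
a standardised *texture* shift of the *intermediate* habitat: its
log-smoothness moves down by `effect_size * 0.1` (sharper local structure,
higher realised voxel variance and entropy), two between-patient SDs of
that parameter at the default effect size of 2. Both the compartment and
the modality of the signal are structural choices, not cosmetic ones. In a
stratified phantom the whole-tumour feature set can focus on the
extreme-intensity strata without any clustering: order statistics
(maximum, 90th percentile) read the brightest shell directly, and the
high/low-gray-level-emphasis texture families are gray-level-conditioned
summaries that isolate the extreme habitats by construction — a signal
planted in the rim or the core is therefore *not* habitat-local, and
whole-tumour models see it at nearly full strength. Likewise a mean-
intensity shift anywhere moves gray-binned global summaries. A texture
shift in a minority intermediate stratum (fractions 0.2 / 0.2 / 0.6 in the
planted-signal study) is different: the whole-VOI median sits outside the
stratum (the cumulative fraction below it is 0.4), whole-tumour variance
is dominated by the between-habitat intensity spread so the stratum's
amplitude change is invisible to it, no emphasis family conditions on
middle gray levels, and the min-max anchors are set by the stable extreme
habitats. Only in that regime is a habitat-exclusive signal even
expressible — precisely the regime the habitat method exists for.

**What passing phantom tests does not show.** The phantoms have no
acquisition physics (no bias field, no Rician noise), a single geometry
family, exact habitat-truth labels, and one imaging sequence; habitat
boundaries in real tumours are neither concentric nor sharp, and real
habitat signal is unlikely to be as cleanly parameterised. Phantom results
validate the *machinery* — that each stage recovers what was planted at
realistic sizes and noise levels — not clinical performance. The published
patient-level AUCs cannot be reproduced without the original images, and
the package does not claim them.

## Numerical choices and degenerate inputs

- Seeds: one master seed fans out to every stage, replicate and patient
  through a multiplicative string-hash (`derive_seed`), so any artifact is
  reproducible from `(config, seed)` and streams never collide.
- k-means: k-means++ seeding with 10 restarts and Lloyd iterations capped
  at 300 (50 inside consensus replicates); restarts that empty a cluster
  are redrawn; inputs with at most k distinct points are assigned by
  distinct value with zero WCSS.
- Consensus pairs never co-sampled are excluded from the CDF with a
  warning; the area-under-CDF sequence is checked to be non-decreasing.
- Texture matrices of single-gray-level regions produce the conventional
  limits (contrast 0, correlation 1); non-finite feature values are mapped
  to 0 so downstream matrices never carry NaN.
- Constant VOIs normalise to the range minimum; zero-variance features are
  an explicit error in z-scoring and are silently dropped before the ICC
  screen only when the screen itself removed the variance source.
- Empty masks, non-binary masks, grid mismatches and resampling that
  empties a mask are explicit, named errors.

## Problem sizes used in the bundled experiments

The test-suite and the acceptance script run at desk scale, chosen to keep
statistical margins while staying fast: habitat-recovery checks use 10
default phantoms; k-selection recovery uses cohorts of 5 phantoms, 200
consensus replicates over 2000 pooled voxels, candidates 2..10; the
planted-signal study uses 120 training and 60 test phantoms per replicate
with effect size 2, repeated over independent seeds; LASSO recovery uses
n = 200 with 5 informative and 95 noise features. The pipeline smoke
configuration (12 + 6 phantoms, 50 consensus replicates) exercises every
stage in seconds.

## Known limitations

- The native radiomics engine implements a fixed IBSI-style subset; it does
  not reproduce any particular extractor's naming or exact feature list.
- r x c tables use the chi-square (with a Fisher recommendation); an exact
  network-algorithm Fisher test for r x c is out of scope.
- Consensus clustering stores an items x items matrix; the default caps at
  5000 pooled voxels for memory reasons.
- The SVM hyperparameter search is a small fixed grid; nested
  cross-validation for unbiased performance estimation is not included.
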
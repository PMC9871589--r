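---
title: "Multi-task 3D convolutional modelling of early psychosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task 3D convolutional modelling of early psychosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early psychosis (EP) shows only mild structural brain changes, which makes
individual-level classification from structural MRI harder than in chronic
schizophrenia. Because cognitive impairment is a core feature of psychosis,
`epcog` implements a multi-task approach: a single 3D convolutional encoder
reads gray-matter (GM) and white-matter (WM) tissue-probability volumes and
feeds three independent MLP subbranches —

* **EP**: a two-way diagnosis classifier (EP versus healthy control, HC);
* **CLC**: cognitive-*level* classification, one n-way softmax per
  cognition dimension after equal-width binning of the scores;
* **CLR**: cognitive-*level* regression, one continuous output per
  dimension in standardized score units.

The hypothesis encoded by the architecture is that forcing the shared
encoder to also predict cognition injects clinically relevant structure
into the representation and thereby helps the diagnosis head.

The six cognition dimensions follow the MATRICS Consensus Cognitive
Battery: processing speed (PSp), vigilance (Vig), working memory (WMe),
verbal learning (VeL), visual learning (ViL) and problem solving (PSo),
all on T-score-like scales (population mean roughly 50, SD roughly 10).

## Input contract and preprocessing

The package consumes the *outputs* of a standard voxel-based-morphometry
segmentation pipeline: per-subject GM and WM probability maps, already
skull-stripped and registered to a common space, with voxel values in
\[0, 1\]. Segmentation itself is out of scope. Maps are clamped to \[0, 1\]
on load (segmenters occasionally emit tiny float excursions), optionally
down-sampled by voxel-centre-aligned trilinear interpolation
(`resample_volume()`; each axis is rescaled independently, so anisotropic
source grids are accepted), and stacked into an H x W x D x 2 array with
fixed channel order (GM, WM). When only one tissue is available the map is
replicated into both channels so the input dimensionality never changes.

Cognition preprocessing has three steps, each fitted on a *training*
subject set and then applied everywhere:

1. **Mean imputation** (`impute_missing()`): a missing cell is replaced by
   the mean of the observed values of its dimension. Observed cells are
   untouched, so observed means are preserved exactly.
2. **Equal-width binning** (`fit_binning()` / `apply_binning()`): each
   dimension's \[min, max\] range is split into n equal parts; since ranges
   differ per dimension, so do interval widths. Ties at interior edges go
   to the upper bin, the maximum falls into the top bin, and out-of-range
   inference scores clamp to the end bins — this makes binning exhaustive
   and exclusive, which an unstated convention would not guarantee.
3. **Standardization** (`standardize_scores()`): per-dimension z-scores
   (population SD) for the regression head; predictions are transformed
   back to original units before error reporting.

Whether the reference statistics (imputation means, bin ranges,
standardization moments) should come from the training split of each fold
or from the whole cohort is genuinely ambiguous in the source material.
The default is the training split, which is leakage-free;
`paper_mode = TRUE` in `cross_validate()` switches to whole-cohort
fitting for comparability with published practice.

## The network

The encoder is a sequence of blocks — 3D convolution (kernel 3, stride 1,
padding 1), batch normalization, rectifier, 2x max-pool — one block per
entry of `conv_channels`, followed by global average pooling (GAP). The
exact layer table of the original architecture is not public; the block
structure is therefore configurable, with `conv_channels = c(16, 32, 64,
128)` as the default. Inputs whose dims are not divisible by
`2^n_blocks` are zero-padded up to the next compatible grid (a 120^3 map
with four blocks pads to 128^3); `pad_input = FALSE` turns this into an
error that names the smallest compatible dims. Each MLP head has one
hidden layer (width 64, rectifier, dropout 0.2). An optional orthogonal
gender embedding (male = (1,0), female = (0,1)) can be concatenated to
the encoder features, reflecting the uneven gender composition of the
motivating cohort (62 male / 15 female).

The CLC head is realized as one n-way softmax group per cognition
dimension from a single subbranch; its loss is the *mean* of the six
per-dimension cross-entropies so it stays scale-comparable with the EP
cross-entropy. The CLR loss is the per-sample squared Euclidean distance
over the six standardized outputs, averaged over the batch. Averaging
(not summing) over the batch keeps learning-rate semantics independent of
batch size. The composite objective is the unweighted sum of the enabled
components plus the regularization term, which is realized as optimizer
weight decay; the reported regularization value is `(wd/2) * sum(theta^2)`
for transparency. Unit component weights are the default; `loss_weights`
exposes them because the balance between the heads is an acknowledged
open point (see "Multi-task interference" below).

All forward and backward passes are implemented in the package (im2col +
BLAS matrix products for the convolutions, with an analytic batch-norm
backward). A finite-difference check of the full composite gradient on a
4^3 toy model agrees with backpropagation to about 1e-10 and is part of
the test suite.

## Training recipe

Defaults follow the published recipe: Adam, starting learning rate 1e-4
decayed by a factor 0.7 after every 60 epochs, weight decay 0.02, batch
size 10, 300 epochs, and data augmentation consisting of a random
left-right flip (p = 0.5) and a rotation about a random principal axis by
an angle uniform in ±10 degrees (the angle range is not stated in the
source; ±10 degrees is a small-perturbation default and configurable).
Augmented volumes are trilinearly resampled and clamped back to \[0, 1\].
`grid_search()` evaluates the published hyperparameter grid (learning
rate in {1e-3, 1e-4, 1e-5}, batch size in {4, 8, 10, 12}, weight decay in
{0, 0.1, 0.2, 0.3, 0.4}) on an inner stratified split of the training
data, never on outer test folds; ties break toward the smaller learning
rate, then batch, then decay.

Two additions stabilize small-cohort behaviour; both are fitted on
training data only:

* **Batch-norm recalibration.** During training, normalization uses batch
  statistics; the exponential running estimates that inference would use
  drift away from them. After the last epoch the running statistics are
  recomputed in one clean pass over the (un-augmented) training set.
* **Decision-threshold calibration.** The EP probability ranks subjects
  well (AUC near 1 on strong synthetic effects) but its offset depends on
  the training trajectory, so a fixed 0.5 cut can sit on the wrong side
  of the whole test set. `cross_validate()` picks the cut that maximizes
  balanced accuracy on the training-split predictions and applies it
  unchanged to the held-out fold.

## Evaluation

`confusion_metrics()` implements accuracy, F1 and specificity exactly as
printed formulas with EP as positive class; a metric whose denominator is
zero is reported as `NA` (an explicit undefined marker) and excluded from
fold aggregation with a logged count — zeroing it would bias the means.
`roc_auc()` is the Mann–Whitney pair-ordering probability with half
credit for ties. `regression_metrics()` reports MAE and R² per dimension;
R² may be negative. `make_folds()` produces stratified k-fold assignments
(diagnosis x gender by default) by shuffling within strata and dealing
round-robin, which guarantees fold sizes within one subject of each other
({16, 16, 15, 15, 15} at n = 77) and per-stratum proportionality within
one subject. `cohort_summary()` reproduces the demographic comparison
table: group means (SD) with pooled-variance two-tailed t-tests for
continuous variables, counts with 1-df Pearson chi-square *without*
continuity correction for categorical ones — the uncorrected statistic is
the one that reproduces both published demographic p-values (0.817 for
gender, 0.852 for ethnicity) from the printed counts. The published
cognitive-score p-values cannot be reproduced from the printed summary
statistics by any pooled or unpooled t-test (processing speed, for
example, gives p near 1e-10, not 1.75e-5); they were most likely computed
on pre-imputation subsets, and the package makes no attempt to guess.

## The synthetic cohort generator

The restricted clinical data cannot ship with the package, so
`simulate_cohort()` generates phantom cohorts with the *statistical*
structure of the motivating dataset: 39 HC / 38 EP, gender 31M/8F versus
31M/7F, ethnicity 28/11 versus 28/10, per-group cognition means and SDs
matching the published cohort table, the published missing-entry counts
(PSp 5, Vig 3, WMe 4, VeL 1, ViL 1, PSo 1; at most one per subject,
missing completely at random), and ages from the published group moments
truncated to the published range.

Imaging is a Gaussian-blob phantom: the GM template is a normalized sum
of `n_blobs` random blobs, WM is the complementary smooth map
`(1 - GM) * envelope`. A latent severity z (standard normal truncated to
\[-3, 3\]; truncation keeps the probability clamping rare) drives both
channels of pathology for patients:

* voxels inside the effect region (a configurable subset of blobs) are
  multiplied by `1 - effect_size * noise_sd * exp(z/4)` — `effect_size`
  is therefore a Cohen's-d-like contrast in units of the voxel noise SD;
* cognition dimension d becomes
  `mean_EP(d) + slope(d) * z * sd_EP(d) + noise`, with the noise SD
  shrunk by `sqrt(1 - slope^2 Var(z))` so the group sample moments
  converge to the calibration targets as n grows (verified at n = 5000
  within 1% in the tests).

Controls have z = 0 and no imaging effect. Default severity loadings are
strongest on PSp, VeL and ViL — the three dimensions with significant
published group differences — at -0.6/-0.6/-0.5, with -0.3/-0.2/-0.3 on
the remaining three; users may override. Default grid is 32^3 (the
generator is a phantom; the real pipeline's 120^3 is available by
configuration), default noise SD 0.05, default effect size 1 with one
effect blob out of twelve.

What the phantom does **not** emulate: anatomy, scanner physics, site and
motion effects, spatially correlated noise, and — importantly — the
*distributed* character of real structural pathology. Passing recovery
tests on this generator demonstrates that the pipeline can find a known
localized signal and that its null behaviour is calibrated; it does not
demonstrate clinical performance.

## What the scaled-down experiments show

The test suite and the acceptance script run the full pipeline at reduced
problem sizes chosen to exercise every stage in minutes rather than GPU
days: recovery and null cohorts of n = 100 at 24^3 voxels with a
c(8, 16, 32) encoder trained 30 epochs at learning rate 1e-3 (a published
grid point), and a multi-task comparison at 16^3, n = 60, 60 epochs. At
these settings the strong-effect cohort (effect size 3) is classified at
about 0.98 mean 5-fold accuracy and the null cohort sits inside the
binomial 95% band around 0.5.

**Multi-task interference.** At desk scale the auxiliary regression does
*not* reproduce the published ordering (EP+CLR above EP-only): with unit
loss weights the per-sample CLR error over six standardized dimensions
starts near 6 while the EP cross-entropy starts near 0.7, and until the
encoder has discovered the effect region the regression residual acts as
a large, noisy gradient that prevents that discovery. A CLR head with
loss weight zero reproduces EP-only behaviour exactly, confirming the
mechanism is gradient competition, not a defect; down-weighting CLR to
1/6 does not rescue it. The published benefit plausibly requires the
original regime — 300 epochs at full resolution on real data, where
cognition correlates with distributed structure rather than a single
implanted blob. The corresponding acceptance check is retained unmodified
and currently fails; this is reported as a scientific finding of the
scaled-down setting rather than hidden by re-weighting or re-tuning.

**Saliency localization.** GradCam and GradCam++ are implemented against
a closed-form oracle (exact to 1e-6 on a one-block toy). On synthetic
cohorts the cohort-mean EP attention map is reliably *elevated* inside
the implanted region (in-region mean exceeds out-region mean for every
patient), but its top-1% voxels do not concentrate there. Two structural
reasons: the encoder ends in global average pooling, so the logit is a
location-agnostic function of channel means and localization can only
come from channel selectivity; and the implanted effect is a GM
*reduction*, whose evidence for the EP logit is activation absence —
exactly what GradCam's rectified positive weighting discards. The strict
top-1% Dice acceptance check therefore also fails at desk scale and is
likewise retained and reported honestly. Saliency maps remain useful as
relative (which-regions-more-than-others) evidence, which is how such
attention maps are normally read.

## Numerical choices and degenerate inputs

* Trilinear interpolation uses voxel-centre alignment and extends border
  values outward; rotations sample outside the grid as zero.
* Batch-norm epsilon is 1e-5; running-statistic momentum 0.1.
* Cross-entropy floors predicted probabilities at 1e-12.
* All-zero input volumes produce finite outputs (batch-norm guards the
  degenerate activation scale).
* Constant score dimensions raise explicit degenerate-range errors in
  binning and standardization rather than producing NaN downstream.
* Every stochastic step (template, subjects, shuffling, dropout,
  augmentation, fold assignment) derives its seed from a user-supplied
  master seed; identical seeds give bit-identical cohorts, training
  histories and metric tables.

## Known limitations

* No GPU path: training is single-threaded CPU (BLAS-backed); the
  defaults in `model_config()` are sized for phantom-scale experiments,
  not 120^3 clinical volumes at 300 epochs.
* The classical baselines (PCA + random forest / RBF support vector
  machine / gradient boosting) accept a precomputed feature CSV in place
  of the morphometry-toolkit features used in the original comparison;
  regenerating those features requires external software that is out of
  scope.
* The generator's missingness is completely at random; the real
  mechanism is unknown.
* Checkpointing stores models as R serializations; no interoperable
  weight format is attempted.
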
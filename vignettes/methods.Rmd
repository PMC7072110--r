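---
title: "Annotation-efficient hand segmentation and bone age regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-efficient hand segmentation and bone age regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bone age assessment (BAA) estimates skeletal maturity, in months, from a
left-hand radiograph; the gap between bone age and chronological age flags
growth disorders. A fully automated BAA system has two stages that `handbaa`
implements end to end: (1) segmenting the hand from a raw radiograph so
downstream features are not contaminated by labels, collimator edges and
background, and (2) regressing age from features of the segmented hand.
Precise segmentation networks need many annotated masks, which are expensive
to produce; the central idea here is *query-by-committee (QBC) deep active
learning*, which concentrates the annotation budget on the images a
committee of segmentation networks disagrees about most.

## Synthetic hand phantoms

Real paediatric radiograph collections cannot ship with a package, so every
stage is exercised on procedurally generated hand phantoms: an elliptical
palm plus five finger capsules, rasterized by pixel-centre membership into a
ground-truth mask, and rendered into an 8-bit image as

```
image = contrast * base + brightness + N(0, noise_sd) + artifacts
```

with the base intensity at three levels (background 25, soft tissue 110,
ossified core `140 + 50 * maturity`). The default nuisance ranges —
brightness ±40, contrast 0.7–1.3, Gaussian noise SD 2–8, up to three bright
blobs or border bars per image — emulate collections that vary considerably
in intensity, contrast and brightness, which is exactly what makes robust
segmentation non-trivial on real data. Artifacts are constrained to lie
outside the hand's bounding box so ground-truth masks stay unambiguous.

A latent *maturity* in [0, 1] drives the geometry: the finger-length-to-palm
ratio is the affine, strictly increasing map `0.9 + 0.9 * maturity` (plus
bounded jitter), and age is defined as `round(228 * maturity)`, covering the
0–228 month range of paediatric BAA datasets. This makes downstream age
recovery well-posed: the image geometry carries the age signal, and a
jitter-free configuration makes that signal exact up to pixel rasterization.

What the phantoms deliberately do **not** model: bone texture, carpal
ossification stages, growth plates, anatomical sex differences, DICOM
acquisition physics. Passing tests therefore demonstrate that the
*machinery* (committee training, querying, metric computation, regression)
is correct and that the pipeline recovers a known signal under realistic
nuisance variation — not that the trained networks would transfer to
clinical radiographs.

## Preprocessing

Images are standardized per image to zero mean and unit variance with the
population standard deviation — `(img - mean(img)) / sd(img)` — before
entering a network; a constant image is rejected explicitly rather than
silently divided by zero. Contrast-limited adaptive histogram equalization
(CLAHE) is available with clip limit 2.0 and an 8×8 tile grid by default
(common practice; with one tile and an infinite clip limit it reduces
exactly to global histogram equalization through an integer CDF lookup).
CLAHE is applied to raw intensities *before* standardization when enabled;
whether equalization should precede segmentation training at all is left as
a configuration switch (`preprocessing$clahe`, default off) since either
ordering is defensible. Crops use the tight mask bounding box expanded by a
configurable margin and clipped to the frame.

## The segmentation committee

Each member is a small U-Net: `depth` stages of two 3×3 convolution + ReLU
layers with 2×2 max pooling, a two-layer bottleneck at
`base_filters * 2^depth` channels, a decoder with nearest-neighbour
upsampling and skip concatenation, and a single-channel sigmoid head
(masks are 0/1, so a two-channel softmax would be redundant). The loss is
the pixel-wise cross-entropy **summed** over pixels per image (mini-batches
average the per-image sums), with probabilities clipped at `1e-7` before
logs. The optimizer is Adam. Widths are parameters rather than constants
because the method is architecture-parametric; the published figure of the
"refined" network does not pin numeric channel counts.

Defaults: `depth = 4`, `base_filters = 32` for realistic runs;
`depth = 2`, `base_filters = 4` at desk scale and in tests, where networks
must train in seconds. The desk-scale learning rate is `5e-3` (the
realistic-run default is `1e-3`): tiny networks see only a few hundred
gradient updates in a 20-epoch overfit run, and Adam's per-parameter step is
bounded by the learning rate, so the larger step is what makes those runs
converge. Forward and backward passes are plain BLAS matrix products over
im2col patch matrices; the patch gather/scatter is the only compiled code in
the package.

The *deep feature vector* each member contributes to QBC is the global
average pooling (GAP) of the bottleneck feature maps — length
`base_filters * 2^depth`. The bottleneck is the minimal choice consistent
with taking "the" deepest representation, and GAP matches how the feature
extraction stage flattens backbone tensors.

## Query by committee

A committee of `k ≥ 2` members differs only in initialization seed
(`master_seed + index`). After each training epoch, every member extracts
its feature vector from every unlabeled image; the disagreement score of an
image is the **mean cosine similarity over all k(k−1)/2 member pairs**
(lower = more disagreement = more informative). The published similarity is
defined for a pair only; the mean is the least-committal symmetric extension
to larger committees, and `aggregate = "min"` is available since selecting
by "the lowest similarity" can also be read as a minimum over pairs. Queries
take the `queries_per_epoch` lowest-scoring ids, ascending, with
lexicographic id tie-breaks; the oracle's masks join the labeled pool
starting with the next epoch. The reference schedule is 100 initial labels,
10 queries after each of the first 20 epochs (300 labels total, 200 oracle
calls), then 80 query-free epochs.

The final segmenter is the single member with the best validation Dice on a
held-out split — ensembling members at inference is deliberately out of
scope. The fully supervised baseline (FSL) trains one network on a seeded
random subset of the same annotation budget, which is the fair comparison
arm: same labels count, no selection intelligence.

At desk scale the comparison runs on a 200-phantom pool (initial 20, 5
queries/epoch for 8 epochs, then 10 query-free epochs, k = 3) against an
18-epoch FSL arm at the same 60-label budget, averaged over 3 master seeds.
The phantom task is easy enough that both arms approach Dice 1.0 by the end
of training, so the expected outcome is a near-tie rather than a visible AL
margin; the acceptance check is directional with a small tolerance for
exactly this reason.

## Evaluation metrics

Masks: Dice `2tp/(2tp+fp+fn)`, sensitivity `tp/(tp+fn)`, specificity
`tn/(tn+fp)`, with foreground as the positive class. Degenerate
denominators (e.g. Dice of two empty masks) raise an explicit error rather
than returning a convention value. Ages: MAE, RMSE, and the concordance
correlation coefficient in Lin's form with population moments,
`2 cov(x,y) / (var(x) + var(y) + (mean(x) − mean(y))²)` — the standard
agreement statistic of that name; the source describes CCC only by
citation, so Lin's definition is adopted and tested against its closed-form
worked values.

## Feature extraction and inspection

A feature backbone maps a preprocessed image to a 3-D tensor; GAP flattens
it to one row of the feature matrix. ImageNet-scale pretrained CNNs are
download- and GPU-scale, so the desk-scale backbone is the trained
committee's best encoder (reusing learned hand features); an identity
backbone exists for testing. For inspection, features decompose to 2-D by
incremental PCA (sequential merge-SVD; exact PCA on a single batch) or
kernel PCA (linear or RBF via kernlab, rescaled to the standard
principal-component score convention). The RBF bandwidth defaults to the
median pairwise-distance heuristic since no bandwidth is published. Score
column signs are fixed (largest-magnitude entry positive) so embeddings are
reproducible; rank-deficient feature matrices take a documented degenerate
path with zeroed trailing columns.

## Age regression

Ages are scaled from [0, 228] months to [0, 1] before fitting and projected
back for evaluation; all reported errors are in months. Two regressor
families are provided with the published settings: ε-insensitive linear SVR
(penalty 1.0, stopping tolerance 1e-3, ε fixed at 0.01 scaled units — the
tube width is unpublished) and kernel ridge regression (regularization 1.0).
The source is contradictory about the KRR kernel — "linear" in one place, a
coefficient "3 which leads to a cubic" in another; since the best published
results are labelled linear, the default is a linear kernel with
`poly_degree = 3` exposed as the alternative reading. The "improvement
parameter 1.0" is interpreted as the ridge regularization strength, the only
scalar KRR hyperparameter. KRR centers features and targets inside the fit
(an unpenalized intercept); plain dual KRR has no intercept and cannot
represent the affine maturity-to-age map. The closed-form primal ridge
solution on the same centering is the independent oracle used in tests.

Model selection uses 5-fold cross-validation with seeded shuffled fold
assignment; per-fold metrics are computed in months on the held-out fold and
the pooled report concatenates all fold predictions (single-observation
folds report an undefined CCC as `NA`). Ensembles of KRR: bagging (seeded
bootstrap resamples, mean prediction) and AdaBoost.R2 with linear loss and
weighted-median prediction — the standard regression AdaBoost, since no
variant is published. Sex stratification fits and cross-validates all,
male-only and female-only cohorts; equal-frequency age balancing is
available as optional per-bin downsampling with 12-month bins (bin width
unpublished).

The desk-scale recovery experiment uses 500 jitter-free phantoms at 96×96
(coarser rasters quantize the geometry too heavily for a months-scale
check), five mask geometry features, and additive age noise with SD 6
months; a correct estimator should land near the expected absolute noise
`E|N(0,6)| ≈ 4.8` months, and does.

## Numerical choices and degenerate inputs

* Probabilities are clipped to `[1e-7, 1 − 1e-7]` before logs; sigmoid
  arguments to ±30.
* Max-pool ties route gradients to the first maximal position in a fixed
  window order.
* Query-score ties break lexicographically by id; fold assignment, member
  seeds, bootstrap resamples and shuffles all derive from one seed through
  an integer mixing function, so every entry point is reproducible
  end-to-end from a single global seed.
* Empty masks, constant images, zero feature vectors, zero-variance
  sequences and empty cohorts raise typed errors (or explicit warnings
  where the fit can proceed) instead of propagating NaN.

## Problem sizes

Tests and the acceptance script run tiny configurations by design: 32–96
pixel phantoms, depth-2 networks with 2–4 base filters, pools of 10–400
images, 3 master seeds for paired comparisons, 300–500 phantoms for
regression. These sizes were chosen so a full run completes on one CPU core
in minutes while still exercising every code path at honest scale; none of
them is a statement about the sizes a real deployment would use.

## Known limitations

* Phantom geometry is far simpler than radiograph anatomy; segmentation
  Dice values here do not predict clinical performance.
* The committee is trained member-by-member with no weight sharing; at
  realistic sizes this costs k full trainings per epoch.
* AdaBoost.R2 can stop early when its weighted loss exceeds 0.5; with a
  strong base learner on clean data the ensemble may contain few members.
* The CLI serializes models with R's native serialization; checkpoints are
  versioned but not portable across major R versions.
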
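# handbaa

Annotation-efficient hand segmentation and bone age regression, end to end,
on synthetic hand phantoms.

Bone age assessment (BAA) estimates skeletal maturity in months from a
left-hand radiograph; discrepancy with chronological age flags growth
disorders. Automating BAA requires (1) segmenting the hand from a noisy
radiograph and (2) regressing age from features of the segmented hand —
and accurate segmentation networks normally demand thousands of annotated
masks. `handbaa` implements a pipeline that attacks the annotation cost
with **query-by-committee (QBC) deep active learning**, then performs the
age regression with kernel-ridge ensembles, for researchers studying
annotation-efficient medical image pipelines who want every stage runnable
and testable on a laptop CPU.

## The method

**Segmentation with active learning.** A committee
*C = {θ₁, …, θ_k}* of U-Nets is trained on a shared labeled pool *L*,
each member differing only in its initialization seed. After every epoch,
each member extracts a deep feature vector (global average pooling of its
bottleneck maps) from every unlabeled image; the disagreement score of an
image is the mean pairwise cosine similarity

cos(vᵢ, vⱼ) = vᵢ·vⱼ / (‖vᵢ‖‖vⱼ‖)

over all member pairs. The images with the **lowest** similarity carry the
most information, are annotated by an oracle, and join *L* for subsequent
epochs. Networks minimize the summed pixel-wise cross-entropy
Σᵢ [−yᵢ log ŷᵢ − (1−yᵢ) log(1−ŷᵢ)]. The reference schedule starts from 100
labels and queries 10 images after each of the first 20 epochs — 300
annotations total — then trains 80 more epochs. The comparison arm is a
fully supervised network on a random subset of the same budget.

**Age regression.** Ages are scaled from [0, 228] months to [0, 1]; linear
kernel ridge regression (regularization 1.0) or linear ε-SVR (penalty 1.0,
tolerance 1e-3) map global-average-pooled features to scaled age, evaluated
by 5-fold cross-validation with MAE/RMSE and Lin's concordance correlation
coefficient, for the whole cohort and per sex. Bagging and AdaBoost.R2
ensembles of KRR are provided.

**Synthetic phantoms.** Real radiographs cannot ship with a package, so a
seeded generator renders hand phantoms (elliptical palm + five finger
capsules) with ground-truth masks, nuisance variation in brightness,
contrast, noise and bright artifacts, and a latent maturity that drives
finger-length-to-palm ratio; age = round(228 × maturity). Every stage of
the pipeline is exercised against these phantoms.

## Worked example

```r
library(handbaa)

## a 60-phantom dataset and a small active-learning run
recs <- generate_phantom_records(60, seed = 7)
net  <- unet_config(depth = 2, base_filters = 4, input_size = c(64, 64),
                    seed = 1, learning_rate = 5e-3, batch_size = 2)
al   <- al_config(k = 3, initial_labeled = 10, queries_per_epoch = 5,
                  query_epochs = 4, post_epochs = 6, master_seed = 7)
res  <- run_active_learning(recs[1:10],
                            lapply(recs[11:50], \(r) list(id = r$id, image = r$image)),
                            oracle_from_records(recs), al, net)
tail(res$history$labeled_size, 1)   # 30 labels after 4 query epochs
best <- select_best_member(res$committee, recs[51:60])
evaluate_model_dice(best$model, recs[51:60])

## age regression on mask geometry
X   <- t(sapply(recs, \(r) geometry_features(r$mask)))
age <- sapply(recs, `[[`, "age_months")
cv  <- cross_validate(X, age, regressor_config("krr"), folds = 5, seed = 1)
cv$pooled
```

A run of the full pipeline at this scale prints a segmentation report such
as (from `Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`,
whose segmentation arm uses a 120-phantom pool and a 45-annotation budget):

```
seg_dice_al          0.977   # mean test Dice of the best committee member
seg_dice_fsl         0.985   # fully supervised baseline, same budget
reg_mae_all          4.84    # months, 5-fold CV, 500-phantom age noise sd 6
reg_ccc_all          0.996   # concordance between true and predicted age
```

Read: on easy phantoms both segmentation arms near-saturate (the active
learner matches the supervised baseline at the same budget), and the
regressor recovers the injected age signal down to the noise floor
(E|N(0,6)| ≈ 4.8 months).

## Command line

```sh
Rscript inst/cli/baa.R pipeline --seed 1 --out run1
Rscript inst/cli/baa.R generate --n 100 --seed 2 --out data1
```

Commands: `generate`, `al-train`, `fsl-train`, `segment`, `features`,
`regress`, `evaluate`, `pipeline`; configuration via `--config file.yaml`
(see `default_pipeline_config()`), datasets via a CSV manifest
`id,boneage,male,image,mask` with 0/255 PNG masks.

## Package layout

- `R/phantoms.R` — seeded phantom generator (images, masks, ages, sexes)
- `R/preprocess.R` — standardization, CLAHE, thresholding, mask cropping
- `R/unet.R` — the U-Net: construction, training, prediction, features
- `R/active_learning.R` — committee, disagreement, queries, AL loop, FSL
- `R/metrics.R` — Dice/sensitivity/specificity, MAE/RMSE/CCC
- `R/features.R` — backbones, GAP, incremental/kernel PCA, scatter export
- `R/regression.R` — age scaling, KRR/SVR, CV, ensembles, stratification
- `R/pipeline.R` — configuration, manifests, staged runs, CLI
- `vignettes/methods.Rmd` — modelling choices, defaults and limitations
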
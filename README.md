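# clockvae

Semi-supervised analysis of clock drawing test (CDT) images for dementia
screening, built around a deliberately parsimonious representation: a
variational autoencoder (VAE) with **two** latent dimensions.

The clock drawing test asks a person to draw a clock face, fill in the
numbers, and set the hands to "ten after eleven". Drawings by people with
dementia show characteristic anomalies — eccentric or broken faces,
micrographia, missing or displaced hands — but human scoring is noisy.
`clockvae` implements the alternative: pre-train a VAE on many *unlabelled*
clock rasters so its encoder learns the drawing population, then fine-tune
that encoder with a small labelled cohort to separate dementia (label 1)
from control (label 0) drawings, and finally *operationalize* the 2-D
latent plane itself into labelled decision regions with a k-nearest
neighbour model, so a new drawing can be read off a map.

Because clinical clock images are not publicly distributable, the package
includes a first-class synthetic clock generator with known generative
factors; every stage of the pipeline is developed and tested against it.

## Model

Each drawing is cropped to its largest ink contour, size-filtered
(bounding boxes of 40,000 px or more are discarded), resized to 100×100 by
exact area averaging, and flattened to `x ∈ [0,1]^10000` (ink = 1). The
architecture is

```
encoder: 10,000 → 512 (ReLU) → (μ ∈ R², log σ² ∈ R²)
decoder:      2 → 512 (ReLU) → 10,000 (logistic)
```

trained by minimising the negative ELBO — pixel-summed binary
cross-entropy plus the closed-form Gaussian KL
`½ Σ (μ² + σ² − 1 − log σ²)` — with Adam (batch 16). The classifier reuses
the encoder's mean path and adds a `2 → 512 → 1` logistic head, fine-tuned
jointly for 10 epochs. Evaluation reports AUROC, AUPRC, accuracy, F1,
precision, sensitivity, specificity and NPV with bootstrap confidence
intervals (median and 2.5th/97.5th percentiles over stratified resamples).
The networks and their backpropagation are implemented directly on BLAS
matrix products (verified against finite differences in the test suite),
with an in-place C++ Adam kernel.

## Worked example

```r
library(clockvae)

# 1. synthesize and preprocess an unlabelled pre-training cohort
un <- preprocess_cohort(sample_cohort(cohort_spec(1700, 300, seed = 101)))

# 2. pre-train the VAE (10 epochs for a desk-scale run)
fit <- train_vae(un$x, train_config(epochs = 10, batch_size = 16, seed = 11))
tail(fit$history, 1)
#>    epoch   recon      kl   total
#> 10    10 1596.02 9.23661 1605.26

# 3. fine-tune the encoder on a small labelled cohort
ftc <- preprocess_cohort(sample_cohort(cohort_spec(60, 53, seed = 404)))
clf <- init_from_encoder(fit$params, head_hidden = 512, seed = 1)
ft  <- fine_tune(clf, ftc$x, ftc$y, epochs = 10, seed = 1)

# 4. evaluate on a held-out cohort with bootstrap CIs
tst <- preprocess_cohort(sample_cohort(cohort_spec(50, 50, seed = 505)))
report <- bootstrap_ci(tst$y, predict_proba(ft$params, tst$x),
                       n_boot = 100, seed = 2)

# 5. operationalize the latent plane with kNN (k = 13)
lat <- project_cohort(fit$params, ftc$x)
knn <- fit_knn(lat, ftc$y, k = 13)
rmap <- region_map(knn, resolution = 50)   # dementia/control regions
```

On this synthetic family the code above prints a held-out AUROC of 0.986
with a bootstrap 95% interval of [0.965, 0.998] (the cohorts differ in
eccentricity, hand anomalies and size, and the task is easier than
clinical data), the k = 13 model classifies its own training latents with
0.85 accuracy, and
`traverse(fit$params)` produces a 9×9 montage over `[-4, 4]²` whose
neighbouring reconstructions differ about 3–4× less than opposite ends of
a row — the smooth latent manifold the Gaussian prior induces.
`factor_correlation()` against the generator's ground truth shows which
drawing factors each latent dimension encodes (face size, eccentricity,
boundary completeness are the strongest, mutually entangled).

A full experiment — synthesize → preprocess → pre-train → fine-tune → kNN
→ evaluate → traverse, with per-stage seeds, artifact hashing and resume —
runs from one configuration:

```r
run_pipeline(list(work_dir = "run1", seed = 1))   # defaults mirror the study
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/clockvae.R`.

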
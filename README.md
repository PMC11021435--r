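# lesionbench

Probing what medical-image classifiers actually rely on.

Convolutional networks and attention-based networks reach similar clean
AUROC on lesion classification while using different evidence: different
spatial frequencies, different sensitivity to where a lesion sits, and
different tolerance of noise or of partially hidden findings. This package
implements four behavioural probes of that difference as a tested,
reproducible pipeline:

1. **Corruption robustness** — ΔAUROC = AUROC(clean) − AUROC(corrupted)
   under 16 registered corruptions at severities I1–I5;
2. **Translation consistency** — Consistency = (1/N) Σᵢ 1{y¹ᵢ = y²ᵢ} over
   pairs of random integer translations of the same image, each losing at
   most 7% of the frame;
3. **Occlusion sensitivity** — ΔAUROC when 15/30/45/60% of the lesion's
   bounding box is masked by a random rectangle;
4. **Shape/texture bias** — ΔAUROC under two ablations: *shape-only*
   (lesion interior flattened to a background-ring constant, contour kept)
   and *texture-only* (largest inscribed lesion rectangle stretched to full
   frame, outline discarded).

Around the probes it provides: multi-label AUROC/AUPRC and micro-averaged
confusion metrics with fold-wise 95% intervals (1.96·s/√k); radially
averaged Fourier amplitude profiles of images and of model input
gradients; a per-class weighted two-model ensemble (convex weight 0.75/0.25
on each member's stronger classes) against the unweighted-mean baseline; a
synthetic lesion-image generator whose class signal is carried by boundary
shape, interior texture, or location (with masks, tight boxes and folds);
and two tiny CPU-trainable reference classifiers — a conv+max-pool family
and a patch-embedding+self-attention family — trained with AdamW, cosine
annealing and per-class binary cross-entropy by backpropagation implemented
and verified inside the package.

Real datasets are supported through a manifest interface (PNG images + CSV
of labels, optional masks/boxes, fold ids); nothing is downloaded.

## Worked example

Train the conv family on shape-coded synthetic lesions and measure its
occlusion-degradation curve:

```r
library(lesionbench)

cfg <- synthetic_config("shape", n_per_class = 75, seed = 7001)
ds  <- generate_dataset(cfg)            # 150 images + masks + boxes + folds

clf <- build_classifier(classifier_spec("local_pool", seed = 1),
                        cfg$class_names)
clf <- train_classifier(clf, ds, desk_train_config("local_pool", seed = 1))

ob <- run_obstruction_experiment(ds, clf, seed = 1)
ob$curve
#>   ratio      auroc      delta          ci
#> 1  0.00 0.98915556 0.00000000 0.008078352
#> 2  0.15 0.89964444 0.08951111 0.035099401
#> 3  0.30 0.72853333 0.26062222 0.095409536
#> 4  0.45 0.33964444 0.64951111 0.071428455
#> 5  0.60 0.08711111 0.90204444 0.024109485
```

Reading the table: the clean 150-image training set is classified almost
perfectly (AUROC 0.989). Masking 15% of each lesion's bounding box costs
0.09 AUROC; by 60% masking the boundary evidence this shape-coded model
depends on is gone and ranking inverts (AUROC 0.087, ΔAUROC 0.902). The
`ci` column is the 95% half-width over the five folds. The degradation is
monotone in the masking ratio — the trend the obstruction probe exists to
measure.

The same dataset/model pair feeds the other probes:
`run_robustness_experiment()` (severity-monotone ΔAUROC),
`run_consistency_experiment()` (translation agreement per class),
`run_shape_texture_experiment()` (Δ_shape vs Δ_texture asymmetry), and
`run_ensemble_experiment()` (class-conditional vs general combination of
two prediction sets).

## Layout

```
R/                     implementation (generator, perturbations, decomposition,
                       metrics, frequency, models, ensemble, experiment drivers)
tests/testthat/        unit, property and end-to-end trend tests
scripts/acceptance.R   from-scratch recomputation of the headline numbers
vignettes/             methods vignette: models, parameters, design choices
```
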
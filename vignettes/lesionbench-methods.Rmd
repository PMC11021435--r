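---
title: "What do lesion classifiers actually look at? Methods behind lesionbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{What do lesion classifiers actually look at? Methods behind lesionbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lesionbench)
```

## The problem

Two families of image classifiers dominate medical imaging: networks built
from local convolutions with spatial pooling, and networks built from patch
embeddings with global self-attention. They reach similar headline accuracy
on clean images while relying on different evidence — different spatial
frequencies, different sensitivity to where a lesion sits in the frame,
different tolerance of noise and of partially hidden findings. For a model
that will read radiographs or dermoscopy images in the wild, those
differences matter more than a fraction of a percent of clean AUROC.

`lesionbench` packages four probes of that behaviour — corruption
robustness, translation-consistency, occlusion sensitivity, and
shape/texture cue decomposition — together with a synthetic lesion-image
generator and two tiny trainable reference models, so that every probe can
be exercised end to end on a laptop CPU and verified by tests. Real
datasets enter only through a plain manifest interface (PNG files plus a
CSV of labels, masks, boxes and folds); nothing needs to be downloaded to
use or test the package.

## The synthetic generator

`synthetic_config()` / `generate_dataset()` draw star-shaped lesion blobs
on a noisy linear-gradient background. The boundary is a truncated radial
harmonic star,

$$r(\theta) = r_0\Big(1 + \sum_{k=2}^{6} a_k \cos(k\theta + \phi_k)\Big),$$

with per-image random phases, so boundary complexity is controllable and
measurable (the roughness statistic used in the tests is the normalised
standard deviation of boundary-pixel radii). The interior is filled with
band-pass Gaussian noise around a per-class centre frequency, on a base
intensity of 0.75 against a 0.2–0.5 background gradient, plus Gaussian
pixel noise (sd 0.05). Masks and tight half-open bounding boxes are emitted
for every sample; folds are assigned round-robin.

Exactly one visual channel carries class identity, chosen by `mode`:

* **shape** — class 1 is a smooth disc, class 2 a five-lobed star
  (amplitude 0.35 at $k=5$); texture and position are uninformative.
* **texture** — classes differ in texture band (defaults 1.5 vs 24
  cycles/image-width, i.e. near-homogeneous vs fine-grained); shape and
  position are uninformative.
* **location** — class 1 sits at the frame centre, other classes are
  placed uniformly; appearance is uninformative.

Default geometry was calibrated once so that a tiny classifier can recover
each signal, and then frozen:

* radius 0.25–0.30 of the frame for shape and location data. The narrow
  spread keeps boundary complexity, not lesion size, the dominant shape
  cue; with a wide radius spread the perimeter of a large disc overlaps
  that of a small star and the class becomes a nonlinear function that a
  three-layer network learns unreliably.
* radius 0.25–0.40 for texture data, with texture contrast 0.25. Large
  lesions dominate the frame, which forces interior-appearance detectors
  that do not depend on the surrounding background — exactly the detectors
  that must survive when `texture_only()` magnifies a lesion crop to full
  frame.
* texture bands about four octaves apart with a wide (≈2-octave) pass
  band. The texture-only stretch rescales spatial frequencies by roughly
  the magnification factor (~1.6–3×); a smooth-vs-grainy contrast survives
  that rescaling, whereas two narrow mid-frequency bands can land on each
  other after magnification and invert a frequency-tuned model's ranking.

What the generator does **not** emulate: anatomy, acquisition physics,
label noise, class imbalance (classes are balanced by default — public
training splits rarely state prevalences, so the neutral choice is made
explicit here), co-occurring findings, or colour. Passing trend tests on
this benchmark therefore demonstrates that the pipeline measures what it
claims to measure on data with a known ground-truth mechanism — not that
any particular architecture will behave the same way on CheXpert-scale
radiographs.

`generate_predictions()` supplies the other fixture the evaluation and
ensemble layers need: per-class probability scores with a known
discrimination level, drawn from a binormal model with separation
$d' = \sqrt{2}\,\Phi^{-1}(\mathrm{AUROC})$ and squashed to $[0,1]$ by a
logistic map (rank-preserving, so the realised AUROC converges to the
target). Positives are allocated deterministically as
`round(prevalence * n)` per class, and a shared target matrix can be reused
across several synthetic "member models".

## Perturbations

**Corruptions.** `corrupt()` applies one of sixteen registered corruptions
at integer severities 1–5. The registry covers four noise types, four
blurs, three photometric changes and five digital/geometric distortions;
each corruption has a single controlling parameter, strictly monotone in
severity, tabulated by `corruption_registry()`. Noise corruptions take an
optional seed; everything else is a deterministic function of the input
(the elastic displacement field is drawn from a fixed internal stream per
severity). All corruptions clamp back to $[0,1]$.

**Translations.** `sample_translation_pair()` renders an image twice under
independent integer-pixel shifts drawn uniformly from the set of offsets
whose exact area-loss fraction $1-(W-|dx|)(H-|dy|)/(WH)$ stays within the
budget (default 7%, which at 224 pixels admits $|dx| \le 15$). Shifts are
integer-valued and vacated pixels are zero-filled — both declared
conventions, chosen so the loss bound is exact and no interpolation blurs
the comparison.

**Occlusion.** `occlude()` masks a stated fraction of a lesion's bounding
box with one axis-aligned rectangle, aspect-matched to the box and placed
uniformly at random fully inside it, filled with a constant (default 0).
The covered area is `round(ratio × box area)` up to one row/column of
rounding; pixels outside the occluder are never touched.

## Shape/texture decomposition

`shape_only()` removes interior appearance: every pixel strictly inside
the mask (mask eroded by one pixel) is set to the mean intensity of a
5-pixel background ring around the lesion, so the contour remains visible
but carries no texture. The ring mean (rather than grey or black) avoids
introducing a brightness edge unrelated to shape; the operation is
idempotent. Note one consequence measured by the experiments: the one-pixel
boundary band keeps its original values, so a strongly texture-coded class
retains a faint texture trace at the rim.

`texture_only()` removes shape: the largest axis-aligned rectangle fully
inscribed in the mask (found with a histogram-stack sweep) is resized
bilinearly to a square output frame. Using the inscribed rectangle rather
than the bounding box guarantees zero background contamination; bilinear
resampling cannot overshoot the crop's intensity range. Aspect ratio is not
preserved — the crop is stretched to a square frame, which is the simplest
declared convention.

## Metrics and reports

* `auroc()` is the Mann–Whitney statistic computed from mid-ranks: the
  fraction of positive–negative pairs ranked correctly with ties counting
  one half. It is exact and invariant under monotone transforms.
  `auprc()` is the interpolation-free step-wise area, with tied scores
  processed as blocks.
* `consistency()` is the fraction of decision pairs that agree between two
  renderings of the same images. The underlying statistic is defined for a
  single label per image; for multi-label outputs the package compares
  thresholded per-class decisions (threshold 0.5) and averages over all
  (image, class) pairs, which reduces to the single-label form when there
  is one class.
* `delta_auroc()` reports degradation, clean minus perturbed, per class
  and on the mean, with fold-wise differences propagated to a fresh
  interval.
* `confusion_metrics()` micro-averages one confusion table over all
  (image, class) decisions at a stated threshold, yielding the scalar
  accuracy/F1/specificity/sensitivity/precision used in ensemble reports.
* `cross_val_summary()` returns the fold mean and a 95% half-width
  $1.96\,s/\sqrt{k}$ using the normal approximation. With five folds a
  $t$-quantile would be ~42% wider; the normal form is used because the
  reported intervals are descriptive brackets, not inferential tests, and
  the choice is declared rather than inferred.

## Frequency profiles

`radial_amplitude_profile()` averages the DC-centred 2-D Fourier magnitude
over annular bins of radial frequency (cycles per image width). Bin
amplitudes are root-mean-square magnitudes, so the profile satisfies a
Parseval identity — squared amplitudes weighted by bin populations sum to
the total squared spectral magnitude (diagonal frequencies above the axis
Nyquist fold into the top bin so every coefficient is counted once).

What "the frequencies a model uses" means is genuinely underdetermined;
the package's declared proxy is the input-gradient spectrum:
`sensitivity_spectrum()` differentiates the summed class scores with
respect to the input pixels (exact backpropagation, not finite
differences), takes each gradient map's radial profile, and averages over
images. `spectral_centroid()` condenses a profile to an
amplitude-weighted mean frequency for comparisons. Profiles of images and
of gradient maps are both supported; outputs are labelled by what they
were computed from.

## Reference models

Two deliberately tiny families, built and trained entirely inside the
package (forward passes, backpropagation, AdamW and the cosine schedule are
implemented in base R and verified against numerical differentiation in the
test suite):

* `local_pool`: stacked 3×3 same-padded convolutions, each followed by a
  leaky rectifier and 2×2 max pooling, then global average pooling and a
  linear head. Default 8 channels × 3 blocks at 64×64 input.
* `global_attn`: non-overlapping 8×8 patch embedding plus a learned
  positional encoding, single-head self-attention blocks with residual
  two-layer MLPs and no spatial pooling, a mean-token head. Default
  embedding dimension 16 × 2 blocks.

Both end in an elementwise sigmoid (independent per-class probabilities)
and train with per-class binary cross-entropy under AdamW with cosine
annealing — `train_config()` defaults to learning rate $10^{-4}$.
Three small numerical choices matter and are deliberate: inputs are
centred ($x - 0.5$) so units start half-active; rectifiers are leaky
(negative-side slope 0.1) because with all-positive inputs a large early
step can silence plain ReLU units permanently, which pins the loss at
$\ln 2$; max-pool ties break in a fixed scan order so gradients are
deterministic. `desk_train_config()` carries the minute-scale settings
used by the experiments (local_pool: 20 epochs at rate 0.02; global_attn:
30 epochs at 0.01; batch 16).

The families instantiate the architectural contrast the probes are about:
the pooling pyramid discards absolute position, while the positional
encoding preserves it. On location-coded data this shows up directly in
the translation-consistency experiment, and the test suite asserts the
resulting ordering (conv-pool at least as consistent as attention) on the
mean over five seeds.

## Experiment drivers

Each `run_*_experiment()` function takes an annotated sample list and
trained classifier(s), evaluates fold-wise for confidence half-widths, and
(optionally) writes report CSVs plus a JSON run record containing the
configuration, seed, an MD5 content hash of the dataset and the fold
values. Reruns with identical inputs and seed reproduce every cell; all
randomness (corruption noise, translation offsets, occluder positions)
derives from the experiment seed.

The drivers evaluate a single trained model across folds (the fast
protocol); the full refit-per-fold path exists as `cross_val_predict()`.
Robustness aggregates per-class AUROC → class mean → mean over corruption
types at each severity, in that declared order. Problem sizes used by the
test suite and the acceptance script — 150-sample training sets, 64×64
pixels, 1–3 seeds per trend, 2000-sample score sets for the calibration
and ensemble checks — were chosen as the smallest sizes at which the
trends are stable, and are stated here as the package's benchmark
conditions.

## The ensemble

`class_conditional_ensemble()` combines two aligned prediction sets with a
per-class convex weight: the stronger (or translation-change-insensitive)
member receives weight 0.75 on its selected classes and 0.25 elsewhere,
the default following the published weighting this package re-implements;
`general_ensemble()` is the unweighted mean baseline, and probability
(not logit) averaging is the declared convention.
`select_insensitive_classes()` picks the classes where member B's
per-class value is at least member A's — ties go to B, and an explicit
class list can override the rule when the selection is made by inspection.
Every ensembled probability lies between its member probabilities, and
with base weight 0.5 the two methods coincide exactly.

## Known limitations

* The generator's lesions are single blobs with stationary textures; none
  of the probes here can detect reliance on cues that do not exist in the
  benchmark (markers, rulers, text burns, co-occurring pathology).
* The reference models are orders of magnitude smaller than production
  backbones; trend directions, not magnitudes, are the meaningful output
  at this scale.
* Shape-only ablation necessarily keeps a one-pixel rim of original
  intensity values, so texture-coded classes are not fully erased by it.
* The consistency statistic thresholds probabilities at 0.5; heavily
  miscalibrated models can look spuriously consistent if all their scores
  sit on one side of the threshold.
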
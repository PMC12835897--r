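---
title: "Methods: patch-to-slide aggregation for weakly supervised WSI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-to-slide aggregation for weakly supervised WSI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidewise)
```

## The pipeline and its assumptions

`slidewise` models a whole-slide image (WSI) as a bag of fixed-size
tiles.  The pipeline has two stages with different statistical
characters:

1. **Patch stage.**  A probabilistic classifier maps each 512×512 tissue
   tile to a malignant-class likelihood.  Training labels come from one
   of four policies.  The *supervised* policy uses pathologist ROI
   annotations: a tile whose ROI coverage exceeds θ = 0.8 is malignant,
   a tile with zero coverage is benign, anything in between is discarded
   from training.  The *weak* policy propagates the slide label to every
   tissue tile, which deliberately mislabels the benign tissue on
   malignant slides: if the lesion covers a fraction ρ of tissue tiles,
   the weak patch-label error rate on that slide is exactly 1 − ρ.  The
   *conventional* and *extended* policies control which tiles enter
   training for endpoint tasks (ROI-only vs whole slide); for mutation
   and lymph-node endpoints every selected tile inherits the slide's
   endpoint label, since no sub-slide annotation of those endpoints
   exists.
2. **Slide stage.**  Patch likelihoods are aggregated into slide
   features (below), reduced, and classified.  The working assumption is
   that class information lives in the *distribution* of patch
   likelihoods — malignant slides carry a secondary mode of
   high-likelihood patches — not in any single patch, which is why
   aggregation can outperform the patch-level AUC even when patch labels
   are noisy.

### Slide features

Both slide representations share one discretization of [0, 1] into B
equal-width bins (default B = 10, exposed as `n_bins`); the last bin is
right-closed so a likelihood of exactly 1 is counted.  The Patch
Likelihood Histogram is the per-slide bin-proportion vector.  The
bag-of-words view treats each tile's bin id as a word and weights the
within-slide term frequencies by the smoothed inverse document
frequency ln((1+N)/(1+df)) + 1, then L2-normalizes.  Using the bin ids
as the vocabulary is a design choice: the likelihood bins are the only
discretization the pipeline defines, and sharing edges between PLH and
BoW makes the two blocks directly comparable.  (A k-means vocabulary
over embeddings would fit behind the same `tokenize()` interface but is
not the default.)  The idf weights and the bin edges are fit on
training slides only and applied unchanged to held-out slides.

### Selection and slide classifiers

Fused features are z-scored with training-split statistics (sample
standard deviation; constant features are flagged and passed through
centered).  Feature pairs with |Pearson r| ≥ 0.9 are deduplicated by a
greedy forward scan that keeps the earlier-indexed feature — an
order-dependent but deterministic rule, matching common radiomics
practice.  LASSO then selects the features with nonzero coefficients at
the λ* minimizing 10-fold cross-validated MSE over a 100-point
log-spaced path spanning four decades below the all-zero λ (the binary
label is treated as a numeric response so the tuning criterion is MSE;
a logistic variant sits behind `family = "binomial"`).

One numerical caveat is documented rather than hidden: λ\*-at-minimum
reliably *includes* a strong planted support but tends to overselect —
in the package's planted-recovery benchmark (n = 200, 12 features,
y = 3x₁ − 2x₂ + ε) it keeps the true pair in 20/20 seeds but exceeds
six selected features in a quarter of them.  The one-standard-error
rule (`rule = "1se"`) selects exactly the planted pair in the same
benchmark.  The default remains the MSE minimum because that is the
criterion the pipeline is defined around; users wanting sparser panels
should switch the rule, not tighten λ by hand.

The slide classifiers are L2-regularized logistic regression (penalty
grid searched), an RBF SVM with Platt-scaled probabilities (cost/γ
grid), and a random forest (trees and `maxnodes` grid), each tuned by
stratified inner CV on the training split only and scored by AUC.
Dataset construction mirrors imbalanced-cohort practice: majority-class
undersampling to a stated count, then a stratified 7:3 split with
largest-remainder per-class rounding — chosen because it reproduces the
textbook 60 → 42/18 allocation exactly and keeps every class within one
slide of its global proportion.

### Stain normalization

Stain normalization follows the sparse stain-separation approach: RGB
is mapped to optical density od = −ln(I/I₀) with I₀ = 255 (zeros
clipped to 1), pixels with OD norm below 0.15 are treated as background
and excluded, and the tissue OD matrix is factored as V ≈ WH with a
3×2 non-negative, column-unit-norm basis W and non-negative
concentrations H under an L1 penalty (λ = 0.1) on H.  The solver is
multiplicative updates (200 iterations or relative objective change
< 1e-4) from a deterministic, seeded perturbation of canonical
hematoxylin/eosin vectors; columns are ordered by cosine similarity to
canonical hematoxylin.  Concentrations for normalization are recovered
by an exact two-variable non-negative least-squares solve per pixel,
rescaled by the ratio of 99th-percentile concentration maxima, and
re-rendered with the target basis.  A numerically rank-one OD matrix
(second singular value < 2% of the first) raises a degenerate-basis
warning because the second stain is unidentifiable; pure-background
images are returned unchanged.

### Patch classifier architecture

The trainable default is a small multilayer perceptron over
block-averaged tile pixels (16×16×3 input, hidden widths 64 and 32,
softmax output), trained with minibatch SGD on cross-entropy using the
standard patch-training recipe as defaults: learning rate 0.001, batch
size 32, 20 epochs.  An MLP rather than a convolutional network is a
deliberate desk-scale choice: no deep-learning framework is among the
package's dependencies, and the synthetic textures the package must
learn differ in channel color statistics and coarse spatial frequency —
both preserved by block averaging — so the MLP meets every contract the
pipeline places on the patch model (held-out accuracy ≥ 0.95 on the
synthetic corpus, calibrated probabilities, penultimate-layer
embeddings, full seed determinism).  The surface is
architecture-agnostic: anything exposing `predict_proba()` and
`embed_patches()` can replace it, and `stub_extractor()` fulfils the
768-dimensional transformer-style feature contract with a fixed seeded
random projection.  Input standardization constants are computed on the
training tiles only, to avoid test leakage.  Tiles discarded at
training time by the supervised rule are still scored at inference:
heatmaps and slide aggregation want full tissue coverage.

### Multiple-instance head

Per-patch feature bags are pooled into one slide embedding either by
the arithmetic mean — the simplest faithful reading of "all patches are
input to the slide-level predictor" — or by a gated tanh-attention
scorer yielding a learned convex combination, which additionally gives
per-patch weights for interpretability.  A logistic layer on the pooled
embedding is trained by full-batch Adam on cross-entropy (default 200
epochs, lr 0.01).  The logistic layer carries an L2 penalty of 0.05:
the head operates in 768 dimensions with order-10² slides, so
ridge-style shrinkage, not the pooling, carries most of the
generalization burden.  Bags can be capped at `max_instances` with
seeded subsampling.

## What the synthetic data emulates — and what it does not

The generators define the package's study conditions:

- **Tiled slides** (`simulate_slide`, `simulate_slide_cohort`): a grid
  of tiles from two Gaussian color fields with class-specific
  sinusoidal "nuclear speckle" (benign: pale pink, low frequency;
  malignant: darker purple, higher frequency), plus near-white blank
  tiles.  Malignant slides plant a contiguous lesion covering ρ of the
  *tissue* tiles (ρ is defined over tissue, mirroring that ROI
  annotations delineate lesional tissue).  Because lesions align with
  tile boundaries, ROI coverage is exactly 0 or 1 per tile and the weak
  label-noise rate is exactly 1 − ρ.
- **Likelihood corpora** (`simulate_likelihood_corpus`): benign slides
  draw all patch likelihoods from Beta(2, 8) (mean 0.2), malignant
  slides draw a per-slide fraction ρ ~ Uniform(0.2, 0.6) from
  Beta(8, 2) (mean 0.8).  These defaults encode a moderately confident
  patch classifier on lesions covering a fifth to three fifths of the
  tissue; real cohorts do not report their lesion-fraction
  distribution, so the range is a fixed, stated choice rather than a
  fitted one.
- **Feature bags** (`simulate_feature_bags`): standard Gaussian
  instances; positive bags shift a witness fraction (default 0.3) by 3
  along one axis, so the mean-pooled class separation is analytically
  shift × witness-rate.

None of this is photorealistic histology.  Passing tests demonstrate
that every algorithmic stage recovers planted structure of the kind it
assumes — distributional shifts in likelihoods, witness instances in
bags, contiguous lesions in tiled rasters — under exact ground truth.
They do not demonstrate clinical performance: real frozen sections add
staining variation beyond a two-stain model, annotation error, scanner
artifacts, and patch classifiers far from Beta-clean likelihoods.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the likelihood-corpus
experiments at 200 slides (100 + 100, 50–200 patches each), the tiled
weak-supervision experiment at 30 training + 20 test slides of 5×5
tiles at 32 px, and the bag experiments at 200 bags of 40 instances in
768 dimensions — sizes chosen so the full pipeline exercises every
stage in seconds per experiment on one CPU.  Every stochastic entry
point funnels its randomness through one seeded generator per call
(`withr::with_seed`), so identical configuration plus seed reproduces
outputs byte for byte, and no call disturbs the caller's RNG state.

## Known limitations

- Slide-level (not patient-level) splitting; with multiple slides per
  patient this would be a leakage source.
- The supervised threshold reads "over 80%" strictly: coverage exactly
  0.8 is discarded.  Both θ and the conventional-policy inclusion
  threshold are configurable.
- The Pearson filter's keep-earlier rule makes the kept set depend on
  feature order (deterministically).
- Mean pooling discards spatial arrangement entirely; the attention
  pooler weighs patches but still ignores their positions.
- The pyramidal-format readers of production WSI stacks (mrxs,
  OpenSlide levels) are out of scope; inputs are plain rasters, PNG
  masks, or GeoJSON polygons.
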
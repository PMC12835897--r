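# slidewise

Patch-to-slide aggregation for weakly supervised whole-slide image
(WSI) classification.

## What problem this solves

Intraoperative frozen sections of thyroid nodules must be read under
time pressure, on lower-quality tissue than paraffin sections, and often
without enough specialist pathologists.  A practical computational aid
works at two levels: a *patch* classifier scores 512×512 tiles cropped
from the gigapixel slide, and a *slide-level* model aggregates thousands
of patch scores into one diagnostic call — benign vs malignant, BRAF
V600E mutation status, or lymph-node metastasis (LNM).  `slidewise`
implements that whole patch-to-WSI pipeline for R users: researchers in
computational pathology who want a tested, desk-scale, fully inspectable
implementation of each stage, from tile bookkeeping to the final ROC
curve, without any dependency on clinical slide archives.

## The method

For slide $s$ with tissue tiles $t = 1,\dots,n_s$, a patch classifier
emits likelihoods $p_{st} = \Pr(\text{malignant} \mid \text{tile } t)$.
Two slide representations are built from the same discretization of
$[0,1]$ into $B$ equal-width bins:

- **PLH (Patch Likelihood Histogram):** $h_b(s) = \frac{1}{n_s}\,\#\{t :
  p_{st} \in \text{bin } b\}$, the normalized histogram of patch
  likelihoods.
- **BoW/TF-IDF:** each tile becomes the "word" of its likelihood bin;
  slides become word-count documents, re-weighted by
  $\mathrm{tf}(b,s)\cdot\left[\ln\frac{1+N}{1+\mathrm{df}(b)}+1\right]$
  and L2-normalized, with idf fit on training slides only.

The fused vector $[h(s), \mathrm{tfidf}(s)]$ is z-scored, pruned of
feature pairs with $|r| \ge 0.9$ (Pearson, earlier index kept), and
reduced by LASSO at the $\lambda$ minimizing 10-fold cross-validated
MSE; features with nonzero coefficients feed logistic-regression, SVM
(RBF, Platt-scaled) and random-forest slide classifiers tuned by inner
CV.  Evaluation uses the empirical ROC (trapezoidal AUC = Mann–Whitney
statistic) plus accuracy / precision / sensitivity / F1 at threshold
0.5, and per-slide probability maps for localization.

Around this core the package provides: sliding-window tiling with blank
filtering and exact ROI-coverage fractions (mask or GeoJSON polygon);
Vahadane-style stain normalization by sparse non-negative stain
separation; the four patch-labeling strategies (supervised "over 80%
ROI coverage" rule with discards, weak slide-label propagation,
ROI-only, whole-slide); a small trainable patch classifier (SGD,
cross-entropy, lr 0.001, batch 32, 20 epochs) with a 768-dimensional
feature-extractor contract; and a multiple-instance head (mean or
gated-attention pooling over per-patch feature bags) for the weakly
supervised LNM-style pathway.

Because clinical WSIs cannot ship with a package, a first-class
synthetic-data module generates (i) tiled two-texture slides with a
planted lesion covering a fraction ρ of tissue tiles, (ii) Beta-mixture
patch-likelihood corpora, and (iii) planted-witness Gaussian feature
bags — each with the statistical structure the corresponding pipeline
stage assumes, so every claim in the test suite is checked against
known ground truth.

## Worked example

```r
library(slidewise)

# a synthetic cohort of 80 slides: benign slides draw patch likelihoods
# from Beta(2, 8); malignant slides mix in a Beta(8, 2) component over
# 20-60% of their patches
corpus <- simulate_likelihood_corpus(
  likelihood_sim_config(n_slides = 80, n_patches = c(50, 200), seed = 7))

res <- run_slide_pipeline(corpus$bags, corpus$labels, seed = 7)

res$reports[[res$best]]
#> Slide-level evaluation (n = 24, threshold = 0.5)
#>   AUC 1.000 | accuracy 1.000 | precision 1.000 | sensitivity 1.000 | F1 1.000

round(c(patch_auc = res$patch_auc, slide_auc = res$slide_auc), 3)
#> patch_auc slide_auc
#>     0.707     1.000

res$selection$report
#> LASSO selection: 8 features at lambda* = 0.008312
```

The numbers tell the pipeline's central story: individual patch
likelihoods discriminate only weakly when every patch inherits its
slide's label (AUC 0.707 — malignant slides are mostly benign tissue),
but the aggregated slide-level features separate the classes perfectly
on the held-out 30% (AUC 1.000), with eight histogram features carrying
the signal — the high-likelihood bins get positive LASSO coefficients,
the low bins negative ones.

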
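---
title: "Attention-based multiple instance learning for whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multiple instance learning for whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Molecular markers of a tumor — here the canonical example is estrogen
receptor status (ER+/ER−) in breast cancer — are determined by
immunohistochemistry, but the routine H&E morphology slide already carries
correlated signal. Predicting the marker directly from the H&E whole-slide
image (WSI) is a *weakly supervised* problem: the label is known per slide,
while the morphology that carries it occupies an unknown, often small,
subset of the tissue. `wsimil` implements the standard formalization,
multiple instance learning (MIL): a slide is a *bag* of tile *instances*; a
positive bag contains at least one positive instance, a negative bag
contains none. The *witness rate* — the fraction of instances that carry
the signal — is the main difficulty knob.

## The model

Each 256×256 tile of a bag of $N$ tiles is mapped to a 512-dimensional
embedding $h_i$ by a feature extractor; an attention module scores each
embedding,

$$a_i = \frac{\exp\{w^\top \tanh(V h_i + c)\}}
            {\sum_j \exp\{w^\top \tanh(V h_j + c)\}},$$

with $V \in \mathbb{R}^{128\times 512}$ and $w \in \mathbb{R}^{128}$; the
bag representation is the convex combination $z = \sum_i a_i h_i$, and a
linear decision layer with a sigmoid turns $z$ into the bag probability
$p = \sigma(u^\top z + b)$. The attention weights are non-negative and sum
to one, so they are directly interpretable as the share of the decision
each tile carries. Replacing the attention weighting by the column mean or
column max of the embedding matrix gives the Meanpool and Maxpool
baselines; scoring tiles individually (no pooling, slide score = mean of 50
patch probabilities) gives the single-patch baseline.

### The feature extractor in this implementation

The reference architecture feeds an ImageNet-pretrained ResNet-50 (keeping
its final 1000-dimensional linear layer, dropping only the softmax) into
two fully connected layers (1000 → 512 → 512, ReLU, dropout 0.5). No
deep-learning runtime is part of this package's stack, and a pretrained
CNN is deliberately *not* what the tests should depend on. `wsimil`
therefore uses a **fixed multi-scale filter-bank encoder** as its default
backbone: a box-filter scale space of the luminance channel, band-pass
(difference-of-means) energies at four scales, gradient energy and color
statistics, pooled over a 4×4 spatial grid plus global summaries — 256
deterministic features per tile (`backbone_config()`,
`backbone_features()`). The two FC layers (He-initialized, dropout 0.5),
the attention module and the decision layer are trained on top exactly as
in the reference architecture, with hand-derived backpropagation verified
against finite differences in the test suite.

This frozen-encoder / trained-head split is the standard desk-scale MIL
recipe in computational pathology: it makes per-tile features cacheable
(`build_feature_store()`), so the full training protocol runs in minutes
on one CPU, while every learnable component the attention mechanism
depends on is still trained end to end. The backbone is a pluggable
configuration object, so a CNN encoder can be substituted without touching
the training engine. Object *size and density* — the axis separating the
synthetic positive and negative morphologies — appears in the descriptor
as the distribution of band-pass energy across scales, so the encoder can
represent the signal but nothing in it knows which class is which.

## Training protocol

`train_config()` carries the reference protocol defaults: bags of $N = 50$
tiles drawn uniformly per slide visit, binary cross-entropy, Adam with
learning rate $10^{-5}$ and weight decay $5\times10^{-5}$ for 500 epochs,
exact 50–50 balanced sampling per epoch (the minority class oversampled),
hard-negative mining (the top $\lceil rB \rceil$ highest-loss bags of each
epoch, $r = 0.25$, revisited once at epoch end), and the augmentation
stack: left-right flip (p = 0.5), rotation from {0°, 90°, 180°, 270°},
color jitter, one cutout square of side 100 filled with the dataset mean
pixel, then whole-tile replacement by the constant mean-pixel image with
probability 0.75 (mean-pixel regularization). Augmentation applies at
training time only; evaluation bags are never augmented or replaced.

Decisions the protocol leaves open, fixed here and recorded in the
configuration:

* **Order of operations**: flip → rotate → jitter → cutout per tile, then
  mean-pixel replacement per bag; replacement is not used at test time.
* **Jitter magnitudes**: brightness/contrast/saturation half-range 0.25,
  hue 0.04 — unstated upstream, configurable in `augment_config()`.
* **Cutout fill** is the dataset mean pixel, consistent with mean-pixel
  regularization; the square clips at borders.
* **Slides with fewer than N tiles**: every tile enters once, the
  remainder is drawn with replacement — bag size stays exactly N without
  fabricating pixels.
* **Hard-negative mining** is operationalized as top-loss-bag revisiting;
  the cited object-detection form (online hard example mining) has no
  canonical MIL translation, so the retention fraction is explicit
  configuration, not a claim about the original.
* **Bags per slide per epoch**: one fresh bag — epoch cost stays linear in
  the number of slides.
* **Dataset mean pixel** and feature standardization are training-split
  statistics; they are stored in the model/config and never recomputed on
  evaluation data.

### Desk-scale preset

`desk_config()` is the package's small-cohort preset used by the examples
and the acceptance script: 40 epochs, bag size 20, learning rate $10^{-3}$,
augmentation off. The learning rate differs from the reference protocol
because here the head trains from scratch for 40 epochs rather than
fine-tuning a pretrained backbone for 500; the protocol structure
(balanced sampling, mining, Adam + BCE, multi-bag inference) is unchanged.
The standard experiment in the tests uses 80 slides of 8×8 tiles of 64 px
(a 60/20 patient-grouped split), which keeps a full run in single-digit
CPU-minutes.

## Inference and evaluation

A slide's probability is the mean (optionally median) of `n_bags`
independently sampled, un-augmented bags (`predict_slide()`; default 16,
the tests use 8). Evaluation follows the reference recipe exactly
(`eval_stats`): Mann–Whitney AUC (ties one half), percentile bootstrap CI
from 1000 slide-level resamples, sensitivity/specificity at the decision
threshold (0.25 by default, boundary inclusive), PPV/NPV from the printed
prevalence formulas, the paired DeLong test via structural components for
same-cohort model comparisons, and the upper-tail F-test whose numerator
is the variance of group AUC point estimates and whose denominator is the
pooled within-group bootstrap variance, referred to $F(g-1, \infty)$ —
formally a scaled chi-square test, implemented exactly as stated.
Resamples that lose a class are redrawn; identical score vectors make the
DeLong test degenerate (p = 1, flagged).

## Synthetic cohorts

`generate_cohort()` renders seeded slide mosaics with known slide labels
and per-tile ground truth, so every stage is testable without restricted
clinical data. Background tiles are near-white (all channels ≥ 230 before
noise); tissue tiles share one stained base-color distribution and differ
only in object statistics: positive morphology is dense, small, round
(loosely: uniform cells with small nuclei), negative morphology sparse,
large, irregular (loosely: pleomorphic nuclei). Both classes target the
same expected object coverage (10%), so mean intensity is matched and the
class signal is *not* recoverable from global color — it must come from
local texture, which is what forces the attention mechanism rather than a
color shortcut to carry the decision. Witness tiles are placed uniformly
at random among tissue cells (a contiguous-region option exists for
heatmap demos); a positive slide always contains at least one. Gaussian
pixel noise (SD 3 by default) is added and the mosaic is stored as
lossless 8-bit PNG.

What the generator does **not** emulate: H&E stain chemistry and stain
variability across centers, scanner pyramids and optical blur, pen
markings, tissue-boundary gradients, and spatial correlation of morphology
beyond the tile grid. Tests passing on these cohorts demonstrate that the
algorithmic machinery (segmentation, bagging, attention learning,
statistics) is correct and that attention finds planted witnesses; they do
not certify clinical performance on real WSIs.

## Tiling

Segmentation runs on a thumbnail (default 32× block-mean downsampling):
ITU-R 601 luminance, 256-bin histogram, Otsu's threshold (ties to the
smallest maximizing level; single-bin histograms are flagged degenerate),
tissue = the darker class (H&E absorbs light; `tissue_bright` flips the
rule for other modalities). Tiles are enumerated on the non-overlapping
grid anchored at (0,0); partial right/bottom tiles are dropped rather than
padded; a tile is retained iff at least 1% of its pixels are tissue
(`min_foreground = 0.01`). The thumbnail scale and grayscale convention
are recorded as TileSet metadata, not claimed as the reference values.

## Interpretability

`exhaustive_embed()` reads "bags sampled exhaustively" as a seeded random
partition of all retained tiles into size-N bags (the last padded by
resampling, flagged); per-tile attention is renormalized across the slide
and the slide embedding is the attention-mass-weighted mean of per-bag
aggregates — the combination rule is this package's convention, recorded
here because the source procedure does not specify one. Slides are
clustered by k-means over these embeddings with k selected by the elbow
method, operationalized as the kneedle point (maximum gap below the chord)
of the inertia-vs-k curve under multi-restart k-means; clusters at least
80% predicted-positive or predicted-negative are flagged. Within flagged
clusters, the top 1% of tiles per slide by attention are clustered again
(on the 512-d post-FC embeddings — the features the attention module
actually scores), and each tile cluster yields a panel of up to five
tiles from distinct slides ordered by centroid distance.
`attention_heatmap()` paints per-tile attention over the slide and
outlines the top-quantile tiles. On synthetic cohorts the cluster purity
is reported against predicted labels (as in the source procedure) while
ground truth remains available for checking.

## Numerical choices and degenerate inputs

* Softmax and BCE are computed in numerically stable forms (max-shifted
  exponentials; probabilities clipped at $10^{-12}$).
* Otsu on a histogram with all mass in one bin returns that bin with a
  degenerate flag; a uniform slide segments to all-background with a
  warning.
* Bootstrap resamples that lose a class are redrawn (bounded retries);
  `ppv_npv` returns `NA` with an `undefined` attribute instead of
  propagating 0/0.
* Feature standardization guards near-constant features with unit scale;
  dropout uses inverted scaling so evaluation needs no rescaling.
* Maxpool's reported per-tile weight splits ties evenly so the summary is
  invariant to tile order.
* All randomness flows through explicit seeds; runs restore the caller's
  RNG state.

## Known limitations

* The filter-bank backbone is not a learned representation; morphologies
  separable only through learned hierarchical features would need a CNN
  backbone plugged into `backbone_config()`.
* Pyramidal WSI formats (SVS/NDPI) are out of scope; slides enter as
  plain raster arrays, and the tiling module documents the interface a
  pyramidal reader would implement.
* The bootstrap-pooled-variance F-test inherits the approximations of its
  stated construction; its null calibration is checked by simulation in
  the tests rather than derived.
* Training is single-threaded CPU; the full-scale defaults (500 epochs,
  bag 50, full augmentation) are supported but intended for real cohorts,
  not the synthetic examples.
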
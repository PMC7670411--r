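# wsimil

Attention-based multiple instance learning (MIL) for whole-slide
histology images in R.

Molecular slide-level labels — the motivating example is estrogen
receptor status (ER+/ER−) of breast tumors — can be predicted from
routine H&E morphology, but the signal lives in an unknown subset of a
gigapixel image while only the slide-level label is known. `wsimil`
implements the attention-MIL approach to this weakly supervised problem
for researchers in computational pathology who want a fully seeded,
CPU-scale, end-to-end testable implementation: tissue segmentation and
tiling, bag construction with cutout and mean-pixel regularization, an
attention-pooling network with mean/max-pooling and single-patch
baselines, the training protocol (Adam + BCE, balanced sampling,
hard-negative mining), multi-bag slide inference, the evaluation
statistics, and the attention interpretability workflow. A synthetic
cohort generator with known per-tile ground truth makes every stage
verifiable without restricted clinical data.

## The model

A slide is a *bag* of $N$ tile *instances*; a positive bag contains at
least one positive instance. Tiles are embedded as
$h_i \in \mathbb{R}^{512}$ (two FC layers with dropout 0.5 over a fixed
multi-scale filter-bank tile descriptor), weighted by an attention module

$$a_i = \operatorname{softmax}_i\!\big(w^\top \tanh(V h_i + c)\big),
\qquad z = \sum_{i=1}^{N} a_i h_i,$$

and classified by $p = \sigma(u^\top z + b)$. The attention weights sum
to one and mark the tiles that carry the decision, which drives the
interpretability half of the package (slide clustering with
elbow-selected k, top-1% attention tile panels, heatmaps). Evaluation
follows the standard recipe: Mann–Whitney AUC with percentile-bootstrap
CIs (B = 1000, slide-level resampling), sensitivity/specificity at a
threshold (0.25) with PPV/NPV from the prevalence formulas, the paired
DeLong test, and an upper-tail F-test with bootstrap-pooled variances
for cross-cohort comparisons.

## Worked example

Eighty synthetic slides (8×8 grids of 64-px tiles, 25% background, 50%
prevalence, witness rate 0.2), a 60/20 patient-grouped split, the
desk-scale training preset, and multi-bag inference:

```r
library(wsimil)

spec  <- cohort_spec(n_slides = 80, prevalence = 0.5, witness_rate = 0.2,
                     grid_rows = 8, grid_cols = 8, tile_size = 64,
                     background_fraction = 0.25, seed = 7)
co    <- generate_cohort(spec)
store <- build_feature_store(co, tile_cohort(co))

plan     <- make_splits(co$labels, k = 5, holdout_fraction = 0.25, seed = 11)
test_ids <- plan$slides$slide_id[plan$slides$fold == 0]

fit   <- train_mil(mil_model(backbone = backbone_config(64), seed = 5),
                   store, desk_config(seed = 5),
                   train_ids = setdiff(names(store), test_ids))
preds <- predict_cohort(fit$model, store, ids = test_ids,
                        n_bags = 8, bag_size = 20, seed = 99)

y <- setNames(co$labels$label, co$labels$slide_id)
evaluate_predictions(preds$p_slide, unname(y[preds$slide_id]),
                     threshold = 0.25, B = 1000, seed = 1)
```

```
AUC 1.000 (95% CI 1.000-1.000), n = 20
threshold 0.25: sens 1.000 spec 1.000 prev 0.500  PPV 1.000 NPV 1.000
```

The held-out AUC of 1.0 says the attention model recovered the planted
bag-level signal perfectly at witness rate 0.2 — on this synthetic task
the classes separate completely, so every rate saturates at the 0.25
threshold (real cohorts do not; the low-witness task in the acceptance
script is harder). Where the attention went can be checked against
ground truth:

```r
emb <- embed_cohort(fit$model, store, ids = test_ids, bag_size = 20, seed = 3)
top_attention_tiles(emb, fraction = 0.01)   # top-1% tiles per slide
```

On positive held-out slides the top-attention tiles are overwhelmingly
ground-truth positive tiles (enrichment ≈ 5× the witness rate in this
run), i.e. the model attends to the planted morphology, not a shortcut.

A thin command-line interface wraps the same functions
(`inst/cli/wsimil`): `simulate`, `tile`, `train`, `predict`, `evaluate`,
`interpret`.

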
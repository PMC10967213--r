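---
title: "Pathway-image ConvMixer models for overall-survival classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-image ConvMixer models for overall-survival classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulk gene-expression cohorts with overall-survival (OS) follow-up are
small (hundreds of samples) and wide (thousands of genes). survmixr
recasts OS prediction as binary classification at a chosen horizon —
did the patient die within *t* years, or survive beyond it? — and
feeds a convolutional network not with the raw gene vector but with a
small image whose geometry encodes pathway membership. Interpretation
then works at the pathway level: Grad-CAM says which patches (that is,
which pathways) the trained network attends to.

## From expression matrix to pathway image

Each gene is min-max normalized across samples,
$x_{\text{scaled}} = (x - x_{\min})/(x_{\max} - x_{\min})$, so all
values lie in $[0,1]$; a gene constant across samples maps to zero
rather than being dropped, keeping the image geometry independent of
the data. Training and external cohorts are normalized independently —
they generally come from different platforms, and per-dataset scaling
is exactly what lets external validation probe whether the model
learned biology rather than platform signatures. (A `normalize` flag
on `build_images()` leaves the choice with the caller.)

For every sample, each pathway's genes are laid out in pathway order,
zero-padded to `patch_side^2` entries (missing genes contribute zero
at their position), reshaped row-major into a `patch_side` ×
`patch_side` patch, and the patches are placed row-major on a
`grid_side` × `grid_side` grid. With the defaults (7 and 7) a
40-pathway collection whose longest pathway has 46 genes yields
49-long padded vectors, a 49 × 49 image, and nine trailing blank
patches (the last two of the sixth row and the whole seventh row).
Blank patches stay at zero for every sample and are excluded from all
statistics.

Two conventions the file formats do not pin down are made explicit
here: patches are filled row-major, and pathways occupy grid slots
row-major in collection order. Both are covered by an inverse-lookup
test that reads every pathway vector back out of the image pixel by
pixel. Results depend on the gene order stored in the GMT file, which
is preserved exactly as read.

## Labeling

A record observed beyond the horizon is labeled 0 regardless of event
status; a death within the horizon is labeled 1; a record censored at
or before the horizon is uninformative and dropped. Survival exactly
at the horizon does not count as surviving *beyond* it, so a death at
the horizon is labeled 1 and a censored record at the horizon is
dropped; `boundary = "survived"` flips that convention. Horizon
presets `short`/`mid`/`long` map to 365/1095/1825 days; times must be
supplied in the horizon's unit, and a heuristic warns when magnitudes
suggest a days-versus-years mismatch.

## The network

`survmixer()` fits a compact ConvMixer-style classifier:

* **Patch embedding** — a convolution with kernel = stride =
  `patch_side`, so each patch maps to exactly one spatial position;
  activation, then batch normalization. The default width is 256
  filters.
* **ConvMixer blocks** (two by default) — a depthwise 3 × 3
  convolution with residual connection, then a pointwise 1 × 1
  convolution, each followed by activation and batch normalization.
  The depthwise convolution uses stride 1 with same padding: the
  masking step and Grad-CAM both require every hidden layer to keep
  the grid shape, so shape preservation takes precedence where the
  architecture description is ambiguous about stride.
* **Masking and head** — blank grid slots are zeroed, features are
  global-average-pooled over the grid, and a single linear unit with
  sigmoid produces the death probability. Pooling divides by all
  grid positions (blank zeros included); `gap = "nonblank"` divides
  by the pathway-slot count instead, which only rescales the pooled
  features by a constant.

Because a same-padded depthwise convolution mixes neighboring slots,
blank-slot content could leak into neighboring features. To make
"blank patches are skipped" literally true, blank slots are re-zeroed
after the embedding and after every block. The payoff is a provable
invariance — the model output cannot depend on anything written into
blank patches — which the test suite asserts to below 1e-6 on a
trained model.

Choices the architecture leaves open, fixed here and exposed in
`survmixer_config()`: GELU activation after every convolution (the
ConvMixer convention), conv → activation → norm ordering, no second
residual around the pointwise convolution, binary cross-entropy loss,
and Adam (learning rate 1e-3, batch 32, 50 epochs by default). A
pooled sigmoid without weights cannot classify, so the single linear
unit before the sigmoid is a structural necessity, not an extra.
The whole training loop — forward pass, backpropagation (verified
against central finite differences to ~1e-9 relative), Adam, batch
normalization — is implemented in base R on BLAS matrix products;
training is bit-deterministic given the config seed.

Cohorts of a few hundred samples are easily memorized by even a small
network (training AUC reaches 1.0 while held-out AUC decays), so
the trainer offers the regularization tools usual for this
architecture family: decoupled (AdamW-style) weight decay on the
convolution and linear weights, Gaussian input-noise augmentation,
mixup (convex combinations of sample pairs and their labels), a
cosine learning-rate schedule, and optional early stopping on a
stratified validation split. Noise-plus-mixup with cosine decay is
the recipe the test suite uses; early stopping by validation AUC is
available but noisy for validation sets under ~100 samples, which is
why the fixed cosine schedule is preferred at this scale.

## Validation

`repeated_cv()` runs stratified k-fold cross-validation (defaults
k = 5, 10 repeats = 50 folds): per fold the model is re-initialized
with a derived seed and trained from scratch; the held-out fold gives
the internal AUC, and an optional external dataset — never touched by
training — is scored at the end of every fold. Stratification is used
because fold-level class balance is required for AUC; fold seeds
derive deterministically from the master seed. AUC is the rank
(Mann–Whitney) statistic with ties counted one half.

## Interpretation

Grad-CAM is computed at the output of the last ConvMixer block after
masking (configurable). Per-channel importances are the spatially
averaged gradients of the pre-sigmoid score with respect to the
channel map (Z = 49 positions under the defaults), and the map is the
ReLU of the importance-weighted channel sum. Maps are computed for
the death class for every sample and grouped afterwards by ground-truth
label. Since one grid slot is one pathway, the per-pathway activation
is the scalar at the pathway's slot; blank slots are excluded.

Per pathway, the two label groups are compared with a two-sided
Wilcoxon rank-sum test (exact when both groups have ≤ 10 samples
without ties, otherwise normal approximation with continuity and tie
correction), Bonferroni-corrected over the number of pathways; key
pathways are those with corrected p < 0.05. The correction-then-select
order is deliberate: with 40 tests, a raw p of 0.002 is *not*
significant (corrected p = 0.08). Raw and corrected values are both
reported.

Key pathways are then validated against survival directly: a
rank-based single-sample enrichment score per pathway (gene-wise ECDF
across samples, within-sample gene ranking, Kolmogorov–Smirnov-style
running sum, signed maximum-deviation statistic) feeds a median split
— high group strictly above the median, ties to the low group — and
the two groups are compared with Kaplan–Meier curves and a log-rank
test (via the survival package). The enrichment score follows the
rank-based single-sample family: coordinated up-regulation of a set
pushes the score toward +1, down-regulation toward −1, unstructured
sets toward 0. The kernel-density ECDF refinement found in some
implementations is deliberately omitted; the properties the pipeline
relies on (rank extremity, null centering, monotone response) are
pinned by tests.

## Synthetic cohorts and what they show

`generate_collection()`/`generate_cohort()` produce fully synthetic
data with known ground truth: disjoint pathways (sizes uniform on
3–46 by default, the range of the KEGG "Pathways in Cancer"
collection), per-sample latent pathway activities $a_p \sim N(0,1)$,
member-gene expression $a_p + N(0, \sigma)$ with $\sigma = 0.3$ by
default, min-max scaling, exponential survival times with
$\log \lambda = \log \lambda_0 + \beta \sum_{p \in \text{effect}} a_p$,
and uniform censoring calibrated numerically to the requested rate
(20% by default; $\lambda_0 = \ln 2 / 3$ gives 3-year median survival
at zero risk).

The hazard uses the *sum* of the effect-pathway activities. This is a
deliberate design point: with the default two effect pathways and
effect size 2, the summed-activity risk has standard deviation
$2\sqrt{2} \approx 2.8$, which puts the best achievable
(Bayes-optimal) AUC of the induced 3-year label near 0.95 and makes
"strong signal" genuinely strong. Averaging the activities instead
would shrink the risk spread to $\sqrt{2}$ and cap even a perfect
model near AUC 0.87 — under *any* proportional-hazards time
distribution, because the label depends on the risk only through
$1 - \exp(-c\,e^{\text{risk}})$ — leaving no headroom to distinguish
a good model from a mediocre one.

What passing on synthetic data does **not** show: robustness to
platform batch effects, to the heavy-tailed and zero-inflated marginal
distributions of real RNA-seq/microarray data, to overlapping gene
sets (an overlap option exists but the default collections are
disjoint), or to label noise from mis-recorded follow-up. External
validation on real cohorts remains the only test of those.

## Problem sizes and numerical choices

The test suite and the acceptance script train reduced models — 48
channels for 40 epochs with cosine decay, input noise 0.1 and mixup
0.4, instead of the default 256/50 — on the default study conditions
(n = 400, two effect pathways, effect size 2, noise SD 0.3). These
sizes were chosen once as the package's desk-scale experiment: small
enough to iterate on while leaving the network clearly
over-parameterized for the planted two-pathway signal (on such
cohorts the Bayes-optimal AUC of the 3-year label is roughly
0.93–0.96 depending on the draw, and the trained reduced model lands
within a few points of it). Other numerical conventions: batch-norm epsilon
1e-5 with momentum 0.1 running statistics (inference uses running
stats, which is what makes per-sample Grad-CAM well defined);
constant genes map to zero under min-max scaling; Wilcoxon p-values
on fully tied data are defined as 1; a degenerate median split (all
scores equal) is an error rather than a silent one-group comparison.

## Known limitations

* Pure-R training is CPU-bound; the default 256-channel configuration
  on a 400-sample cohort takes minutes per fit, so repeated CV at
  full width is an overnight job rather than an interactive one.
* The depthwise stride is fixed at 1; strided variants would change
  the grid geometry mid-network and are intentionally unsupported.
* Gene symbols are matched case-sensitively with no alias resolution;
  identifier harmonization belongs upstream.
* The labeling scheme discards censored-within-horizon samples, so
  heavy early censoring shrinks the labeled cohort and can bias the
  label mix; time-to-event losses are out of scope by design.
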
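---
title: "Mahalanobis-metric triplet learning: model, optimization, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mahalanobis-metric triplet learning: model, optimization, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriplet)
```

## The problem and the model

Medical-image classification tasks such as lung-nodule detection on chest
radiographs or benign/malignant calls on cytology records often come with few
labeled examples per class and large within-class variability. **matriplet**
addresses this with metric learning: instead of fitting a softmax classifier,
it learns (a) an embedding $f_w(y)$ of each image and (b) a Mahalanobis
matrix $M \succeq 0$ such that the squared distance

$$ D_M(y_i, y_j) = (f_w(y_i) - f_w(y_j))^\top M\, (f_w(y_i) - f_w(y_j)) $$

is small within a class and large across classes. Classification is then
nearest class centroid under $D_M$.

Training uses triplets $(y, y^+, y^-)$ — an anchor, a same-class positive,
and a different-class negative. With $B = D_M(y, y^+)$, $A = D_M(y, y^-)$,
margin $\alpha$ and pairwise weight $\mu$, the loss over $N$ triplets is

$$ L = \frac{1}{N}\sum_i \Big[ \max\big(0,\; D_x^{(i)}\big) + \mu\, B^{(i)} \Big],
\qquad D_x = 1 - \frac{A}{B + \alpha}. $$

The ratio-form hinge activates exactly when the negative is insufficiently
separated ($A < B + \alpha$), which keeps gradients informative even when
absolute distances are small — the failure mode of the classic additive
triplet loss (`original_triplet_loss()`, kept as an ablation baseline). The
$\mu B$ term shrinks within-class variance independently of the hinge.

### Gradients

Both optimization stages use analytic gradients, derived by the chain rule
through the ratio:

* features: $\partial D_x/\partial A = -1/(B+\alpha)$,
  $\partial D_x/\partial B = A/(B+\alpha)^2$, each acting through
  $(M + M^\top)(f_i - f_j)$ on the corresponding difference vector; the
  pairwise term contributes $\mu (M + M^\top)(f_a - f_p)$ unconditionally
  while the hinge gates the triplet term;
* metric: $\partial D_x/\partial M = -C_{an}/(B+\alpha) +
  A\,C_{ap}/(B+\alpha)^2$ and $\partial D_p/\partial M = C_{ap}$, with
  $C_{ij} = (f_i - f_j)(f_i - f_j)^\top$.

These closed forms are the package's central correctness claim, and the test
suite holds them to $<10^{-4}$ relative error against central finite
differences on randomized fixtures. (A widely circulated variant of the
ratio-loss gradient writes the two metric coefficients as equal and
opposite; those cannot both be partial derivatives of the same ratio, and
the finite-difference oracle is treated as ground truth here.)

### Alternating optimization and the PSD cone

`optimize_alternating()` repeats two stages until the iteration budget:

1. **$M$ fixed** — mini-batch momentum SGD on the network weights through
   the feature gradients and full backpropagation;
2. **weights fixed** — projected gradient descent on $M$: after every step
   $M \leftarrow M - \eta_M \nabla_M L$, the matrix is symmetrized,
   eigendecomposed, its negative eigenvalues zeroed, and reassembled
   (`psd_project()`). Eigenvalue truncation of the symmetrized matrix is the
   Frobenius-nearest point of the PSD cone, so the iterate never leaves the
   feasible set. $M$ starts at the identity.

Batches are K-class × L-image plans (`sample_pk_batch()`) mined for
batch-hard triplets (`mine_hard_triplets()`): per anchor, the farthest
same-class and the nearest different-class member *within the batch*, under
the current $M$, with ties broken to the lowest index. Enumerating all
$N(N-1)M^2(M-1)$ triplets is intractable and unnecessary.

A design point worth recording: stage 2 also mines within freshly sampled
K × L batches rather than over the whole training set. Besides matching the
batch-based sampling scheme, this is statistically important — the hardest
pair over *all* $n$ points is an extreme order statistic whose bias grows
with $n$, and in development it systematically tilted the learned metric
away from the true discriminative direction, while batch-local hardness
recovers it (see "Metric recovery" below).

## The embedding network

The backbone is a bottleneck-residual convolutional network: a stem
convolution (7×7) with 2×2 max pooling, four stages of 1×1 / 3×3 / 1×1
bottleneck blocks with ReLU after every convolution and projection
shortcuts where shape changes, then **spatial pyramid pooling** (SPP), a
fully connected embedding layer, and L2 normalization onto the unit sphere.
SPP partitions the final map into $l \times l$ grids for each level $l$ and
max-pools each cell per channel, so the embedding length
$C\sum_l l^2$ is independent of input size. At full width (2048-channel
map, levels 1/2/4/8) that is $2048 \times 85$ values feeding an 800-d
embedding; bin edges are the half-open $\lfloor iH/l \rfloor$ partitions and
the pooling operator is max, the standard SPP construction.

Two presets are shipped. `"full"` keeps the full-scale topology, including
the non-square 2×1 stride at the entry of the last stage and 128 stem
kernels; it exists for fidelity and is not trainable on a CPU in reasonable
time. `"desk"` preserves the topology at 64×64 inputs (stem 16, widths
16/32/64/128, one block per stage, square strides, SPP levels 1/2/4, 32-d
embedding) — every convolution, pooling, SPP and normalization layer has a
hand-derived backward pass, and the whole chain is finite-difference checked
in the tests. The desk feature map is 4×4, which is why the 8×8 SPP level is
dropped there.

## The attention memory encoder

The attention module is an architectural companion stage: a query vector is
refined over $r$ rounds, each round attending first over a **category fact
memory** (dot-product scores, softmax, weighted readout added to the query)
and then over a **visual fact memory** of image regions (one-layer tanh
scorer with a shared projection to one scalar per region), finishing with
$e_c = \tanh(W_e u_r + b_e)$. Two decoders are provided: a generative LSTM
that emits a category-token distribution per step, and a discriminative
decoder that encodes each candidate with a shared LSTM and softmaxes
dot-product similarities. Three readings were fixed where published
formulations of such encoders are loose: the per-round update writes into a *new* query (the
only reading consistent with "the next round"); the region scorer's
projection must map a k-vector to a scalar per region, so it is a k-vector
with scalar bias rather than a k×d matrix; and the category
memory is a learned per-class embedding table, the minimal structure the
update equations admit.

In the pipeline the two stages compose by sharing the backbone: the final
conv map's spatial positions are the visual memory rows and the region
sequence seeds the query (`attention_encode_image()`). The default
classification path is the metric/nearest-centroid branch; the attention
head is exposed behind a configuration switch because there is no canonical
rule for combining the two branches at inference.

## Synthetic data: what it emulates, what it does not

`generate_blob_images()` emulates the nodule/no-nodule contrast: class 0 is
a low-frequency cosine texture plus pixel noise (background tissue
analogue); class $c \ge 1$ adds $c$ bright Gaussian blobs (amplitude
≈ `contrast` × 90–150 gray levels, σ ≈ 5–12 % of the image side,
emulating the 5–40 mm nodule range relative to a radiograph). It does *not*
reproduce anatomy, acquisition physics, rib/vessel confounders, or the
long-tailed intensity statistics of real radiographs — a desk-scale pass
shows the pipeline learns and classifies; it says nothing about clinical
performance. `generate_tabular()` emulates the Wisconsin cytology records:
nine ordinal features on 1–10, benign rows low (mean ≈ 3), malignant high
(mean ≈ 7), 458 + 241 = 699 rows at the documented cohort counts, with
`inject_missing()`/`drop_missing()` reproducing the 16-incomplete-row
filtering down to 683. The missing marker is the non-numeric `"?"` token of
the public file dialect.

Histogram equalization (`equalize_histogram()`, the classic normalized-CDF
remap over 256 bins, global rather than adaptive) is the enhancement used
for radiographs and defaults ON in the `jsrt-full` preset. The desk preset
leaves it OFF: equalization is a rank remap that stretches the dense
background-texture levels across the full range and compresses the sparse
bright-blob tail, which *reduces* the synthetic fixture's class signal —
the blob generator's `contrast` parameter already plays the role the
enhancement plays for low-contrast radiographs. Resizing uses area
averaging when shrinking and bilinear interpolation when enlarging, both
deterministic.

## Study conditions and numerical choices

* **Desk end-to-end condition:** 2 classes × 50 training and 50 test images
  (64×64, contrast 1.0), desk preset, 20 outer iterations. Desk optimizer
  rates are `lr_w = 0.02`, `lr_M = 0.05`, 4 stage-1 batches and 5 stage-2
  steps per iteration, chosen so the alternating scheme actually converges
  at this scale (loss ≈ 0.98 → 0.03 with nearly all triplets satisfied);
  the generic `train_config()` defaults keep the conservative
  `lr_w = 0.01`, `lr_M = 0.01`.
* **Metric recovery condition:** `generate_planted_features()` draws two
  classes at means $\pm v$ for a random unit direction $v$ with isotropic
  noise — every discriminative bit lies along $v$, so the learned $M$'s
  dominant eigenvector must land near $v$. The default shape (200/class,
  $d = 4$, noise sd 0.3) keeps $v$ statistically identifiable: any
  whitening-style estimator is tilted by the sample-covariance error, which
  scales like $\sqrt{d/N}$; at small $N/d$ the empirical discriminant
  itself sits tens of degrees from $v$ and no correct estimator could meet
  a 15° criterion. Recovery runs use `lr_M = 0.05` over 60 outer
  iterations.
* **Margin and balance defaults:** $\alpha = 1$, $\mu = 0.1$ (configurable;
  the method itself prescribes no values).
* **Degenerate inputs:** $\alpha = 0$ with a coincident anchor/positive
  pair makes the ratio undefined and raises an error; constant images pass
  through equalization unchanged; classes contributing a single batch
  member are skipped by mining, and an all-singleton batch signals an empty
  result rather than fabricating triplets.
* **Ties:** mining and nearest-centroid prediction both break ties to the
  lowest index/class id, making every code path deterministic.
* **Determinism:** every stochastic routine routes through one seeded RNG
  per call and restores the caller's RNG state; identical seeds give
  bit-identical datasets, initializations, batch plans, and fitted models.

## Problem sizes used by the tests

Unit tests run the tiny backbone preset (16×16 inputs) for
finite-difference checks and 2–3 outer iterations for pipeline behaviour;
the acceptance-grade tests run the full desk condition above (about two
minutes) and ten seeded recovery runs (seconds each). These sizes are the
package's documented study conditions, not statements about the limits of
the method.

## Known limitations

* The full-scale preset is shipped but not trainable here; no pretrained
  weights exist, so full-scale radiograph results are out of scope.
* The attention head is architecturally complete and unit-tested but not
  trained by the default pipeline; no joint training rule with the metric
  branch is specified in the source formulation.
* `embed()` accepts any input large enough for the largest SPP level, but
  training always resizes to the configured input size; aspect ratios are
  squared by the resize.
* The metric stage optimizes the full $d \times d$ matrix; no low-rank
  factorization is attempted.
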
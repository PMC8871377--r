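---
title: "Methods: constrained embeddings and local outlier factors for OCT anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained embeddings and local outlier factors for OCT anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

octanomaly detects age-related macular degeneration (AMD) in retinal
optical coherence tomography (OCT) B-scans by treating disease as
*novelty* rather than as one class of a balanced classifier. This
vignette records the model, the parameter choices, what the bundled
simulator does and does not emulate, and the numerical decisions that the
test suite pins down.

## 1. The two-stage model

### Stage 1: an embedding under an L2-constrained softmax loss

A convolutional network $f$ maps an image $x$ to a feature vector. The
training objective is the ordinary softmax cross-entropy over the two
training classes (NORMAL, AMD),

$$
\mathcal{L} \;=\; -\frac{1}{M}\sum_{i=1}^{M}
\log \frac{e^{W_{y_i}^\top f(x_i) + b_{y_i}}}
         {\sum_{c} e^{W_{c}^\top f(x_i) + b_{c}}},
\qquad \text{subject to } \lVert f(x_i)\rVert_2 = \alpha ,
$$

with the constraint implemented exactly by an L2-Norm + Scale layer: the
penultimate feature is divided by its norm and multiplied by $\alpha$.
With the magnitude degree of freedom removed, the network can only lower
the loss by rotating class features apart on the $\alpha$-sphere. The
result is a compact, direction-coded arrangement of the normal class —
the geometry on which a density-based outlier score is meaningful.
`l2_softmax_loss()` enforces the contract at evaluation time: features
off the sphere (beyond a small tolerance) raise an error naming the
missing L2-Norm layer.

Defaults follow the study configuration: $\alpha = 5$, batch size 12,
learning rate $10^{-3}$ with Adam, 30 epochs, an 80/20 stratified
train/validation split, and two output classes. The packaged backbone,
`tiny_cnn`, is a pure-R network (two 3×3 convolution + average-pooling
stages, a 64-unit dense layer, the L2-Norm + Scale head, and a
zero-initialized classifier so training starts at loss $\log 2$ exactly)
operating on 32×32 block-averaged grayscale input. A `resnet50` backbone
is part of the interface but raises an informative error: faithful
ResNet-50 training requires a deep-learning runtime that this package
deliberately does not depend on, and a silent low-fidelity imitation
would be worse than an honest refusal.

### Stage 2: Local Outlier Factor novelty scoring

After training, the classifier head is discarded and the features of the
normal training scans form a reference set $R$. For a query $p$ and
$k = 20$:

* the *k-distance* of $p$ is the distance to its $k$-th nearest reference
  point, and the *k-distance neighborhood* $N_k(p)$ contains every
  reference point at or within that distance — ties are included, so
  $|N_k(p)| \ge k$;
* the *reachability distance* is
  $\mathrm{reach}_k(p, o) = \max\{\text{k-distance}(o),\, d(p, o)\}$,
  which smooths the score for queries deep inside a cluster;
* the *local reachability density* is
  $\mathrm{lrd}(p) = 1 \big/ \mathrm{mean}_{o \in N_k(p)}\,
  \mathrm{reach}_k(p, o)$;
* the LOF score is
  $\mathrm{LOF}(p) = \mathrm{mean}_{o \in N_k(p)}\,
  \mathrm{lrd}(o) / \mathrm{lrd}(p)$.

Scores near 1 indicate a query whose neighborhood is as dense as its
neighbors'; scores well above 1 indicate an outlier. The package
implements two modes with one core: a *fit* mode in which each reference
point is scored leave-self-out (the classical definition), and a
*novelty* mode in which queries are scored against $R$ without ever
joining it, so batch scoring is order-independent and single-query
scoring equals batch scoring.

### The decision threshold

The source study never states a threshold, so the package owns this
decision: `oct_fit()` scores the *validation-portion* normal scans (the
20% of normals held out of embedding training) in novelty mode against
the reference set and takes their `quantile = 0.99` score quantile as
$\tau$. These scans are real normals the model never trained on, so their
score distribution is an honest proxy for the false-positive rate: by
construction about 1% of unseen normals will be flagged. When fewer than
five validation normals exist, `calibrate_threshold()` falls back to the
leave-self-out quantile of the reference set itself.

## 2. The synthetic B-scan generator

Clinical OCT datasets cannot ship inside a package, so the study
conditions are provided by a parametric simulator whose defaults *are*
the conditions under test — they were fixed before any end-to-end results
were inspected and are not tuned to them.

A scan is a stack of `n_layers` bright bands between 35% and 72% of the
canvas height, sharing a random global tilt (±`tilt_jitter` px), a
parabolic sag, and a small per-band sinusoidal wiggle; bands are rendered
as Gaussian intensity profiles ($\sigma = 2.5$ px) over a dark
background, then multiplicative speckle
$I \mapsto I \cdot \max(0, 1 + \mathcal{N}(0, \mathrm{sd}^2))$ is applied
and the image clipped to $[0, 1]$.

* **Dry AMD**: `drusen_count` Gaussian bumps deform the lowest band (the
  RPE) upward, one per disjoint column segment, so lesions never merge;
  the configuration layer rejects geometries that cannot guarantee
  separation.
* **Wet AMD**: a raised-cosine dome of height `fluid_depth` and compact
  support `fluid_width` elevates all bands around a random central
  column, and the pocket between the elevated RPE and its flat baseline
  is filled with dark serous fluid. A render-time check rejects domes
  that would breach the top of the frame.

What this emulates: the layered morphology that gives OCT its appearance,
the two canonical AMD signatures (drusen, sub-retinal fluid),
speckle-like multiplicative noise, and benign geometric nuisance
variation. What it does not: true speckle statistics (Rayleigh-family,
correlated), vessel shadows, motion artifacts, pathology diversity, or
scanner-specific intensity profiles. It is a controlled test bed, not a
clinical data generator.

Two presets anchor the difficulty dial. `"easy"` (low speckle, large
lesions) is the standard condition: the pipeline should recover it almost
perfectly. `"noise"` sets `layer_contrast = 0` and heavy speckle, so the
images carry *no* label signal and accuracy must collapse to chance —
a negative control that guards against the pipeline hallucinating
separability.

Reproducibility uses counter-based seed splitting: each image's RNG
stream is derived from the dataset seed, its class stream and its index,
so changing one class's count never perturbs another class's pixels, and
derived seeds stay below $2^{31}$.

## 3. Numerical decisions

* **Exact neighbor search.** Reference sets here are hundreds of points;
  full pairwise distances are exact, simple, and fast enough. No
  approximate index is used.
* **Tie-inclusive neighborhoods.** $|N_k(p)| \ge k$ with all ties at the
  k-distance included, per the classical definition; tests exercise exact
  ties constructed by reflection.
* **Duplicate handling.** A neighborhood collapsed onto duplicates gives
  mean reachability 0; its lrd is the $+\infty$ sentinel. Ratios resolve
  as $\infty/\infty := 1$ (duplicates among duplicates are inliers) and
  finite$/\infty := 0$; a finite-density point next to a duplicate
  cluster legitimately scores $+\infty$, never NaN.
* **Metric.** Euclidean by default; a cosine option exists and the test
  suite proves both rank neighbors identically on the $\alpha$-sphere,
  where $d^2 = 2\alpha^2(1 - \cos\theta)$ is monotone in the angle.
* **Per-class accuracy = class recall.** Published per-class tables in
  this literature report, for each class, the one-vs-rest recall under
  the label "accuracy"; `class_metrics()` follows that convention (the
  NORMAL row is computed with the roles swapped), while
  `global_accuracy()` provides the ordinary trace ratio separately. This
  is what lets published confusion matrices be reproduced cell by cell.
* **Rounding at the reporting layer only.** `round_half_up()` (half away
  from zero with a $10^{-9}$ guard against binary representation error)
  is applied by `tidy()` — 2 decimals for percentages, 4 for AUC — while
  report objects retain full precision. One reproduced F1 cell is
  asserted at the value implied by its own confusion matrix rather than
  the published figure, which is internally inconsistent by 0.03 at the
  second decimal.
* **AUC.** The ROC curve sweeps grouped score ties from $(0,0)$ to
  $(1,1)$; trapezoidal integration then equals the tie-corrected
  Mann-Whitney statistic, which the tests verify against an all-pairs
  oracle and pROC.
* **Determinism.** Every stochastic step (init, split, per-epoch
  shuffles, image synthesis) draws from seeds derived by counter
  splitting; seeded reruns are bit-identical. One subtlety worth
  recording: `max.col()` breaks ties randomly by default, which made the
  first epoch's training accuracy (tied logits under the zero-initialized
  classifier) non-deterministic; all call sites use
  `ties.method = "first"`.

## 4. Scale and limitations

Problem sizes throughout the package — hundreds of images, 64-dimensional
features, 32×32 backbone input — are a deliberate desk-scale choice so
that training, scoring and the full test suite run in seconds on a CPU.
The architecture is the study's architecture in miniature, not a
reimplementation of ResNet-50; absolute accuracies on clinical data are
out of reach by design, while every *mechanism* (the constraint geometry,
the LOF mathematics, the calibration, the metrics) is implemented at full
fidelity and tested against independent oracles.

Known limitations: the simulator's realism gap described above; the
binary NORMAL/AMD decision (dry/wet sub-classification is out of scope);
threshold calibration assumes enough normal training scans to hold some
out; and LOF's $O(n_\text{ref}^2)$ memory for the reference distance
matrix, acceptable at this scale but not at clinical-archive scale.
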
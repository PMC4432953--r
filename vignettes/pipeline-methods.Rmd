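---
title: "Methods: representations and evaluation for ISH stack annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representations and evaluation for ISH stack annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the algorithmic choices and the
numerical details behind `ishannotate`. Code chunks are illustrative and not
evaluated when the package is built; the same computations run in the test
suite and in `scripts/acceptance.R`.

## Problem setting

The input is a set of genes, each imaged as a stack of sagittal in situ
hybridization (ISH) brain sections, together with a hierarchical ontology of
brain structures. For every structure, curators record whether the gene's
expression is *undetected* or falls in one of several detected categories
(expression pattern, intensity, density). The task is automated annotation:
predict, per (gene, structure) pair, detected versus undetected from the
images alone. Because a large majority of pairs are undetected, the
multi-category problem is reformulated as one binary classifier per structure
(`binarize()` maps the undetected category to −1 and every other category to
+1); with one classifier per ontology node this yields as many tasks as there
are structures (`n_annotation_tasks()`).

Two brain-wide, fixed-length gene representations are implemented and
compared under an identical evaluation protocol.

## Representation 1: multi-scale bag of visual words

Each section image is area-downsampled by an integer factor (default 4) and
covered with a dense grid of local gradient-orientation descriptors
(`dense_descriptors()`):

* 4 × 4 spatial cells × 8 hard-assigned orientation bins = 128 dimensions;
* cell sizes 4, 8 and 16 pixels (descriptor footprints of 16, 32 and 64
  pixels), grid step 4 pixels;
* descriptors with essentially no gradient energy (squared norm below 1e−10)
  are *counted* but not described — flat background is informative in ISH,
  where most of a section may carry no signal;
* non-zero descriptors are L2-normalized, clamped at 0.2 per component, and
  renormalized, the standard contrast-robust normalization for this family of
  descriptors.

For each scale independently, a visual vocabulary of K = 500 words is learned
by K-means (`build_codebooks()`) on a pool of up to 100,000 descriptors
sampled evenly across the corpus images (`sample_pool()`). Lloyd's algorithm
is restarted several times (default 5) and the restart with the smallest
total within-cluster distance is kept, so the selected objective is
monotonically non-increasing in the number of restarts — a property the test
suite asserts. When Lloyd's algorithm empties a cluster, the restart is
re-drawn from a derived seed (up to 10 times) rather than reseeding single
centroids in place; this keeps every kept restart a clean, fully converged
Lloyd run at exactly K centroids.

A section image becomes, per scale, a histogram over the K words of its
non-zero descriptors plus one extra slot holding the zero-descriptor count
(`quantize()`), i.e. (K + 1) bins; histogram mass therefore equals the
descriptor grid size exactly (a conservation law in the tests). The three
scales concatenate to 501 × 3 = 1503 values per section.

Sections are positioned on a normalized sagittal axis. The observed position
range is divided into 7 equal-width intervals (`assign_intervals()`; the
maximum position is clamped into the last interval), section histograms are
averaged within each interval, and the 7 interval averages are concatenated
(`build_global_bow()`): 501 × 3 × 7 = **10,521** values per gene. Averaging
within intervals makes the representation invariant to the order and number
of sections inside an interval while keeping coarse sagittal localization.
Intervals are computed from the recorded section positions rather than from
section indices so that stacks with unevenly spaced or missing sections
remain comparable.

## Representation 2: tapped convolutional network features

`overfeat_fast_architecture()` describes a fixed, fast-variant convolutional
topology on 231 × 231 × 3 inputs: five convolution/pooling stages followed by
a first fully connected layer. Features are read out ("tapped") after layers
6, 9, 12, 16 and 18, giving vectors of length 36,864 / 73,728 / 147,456 /
36,864 / 3,072 (feature-map counts 256 / 512 / 1024 / 1024 / 3072). The
forward pass is implemented in plain R via im2col + BLAS matrix
multiplication; shape propagation is symbolic (`propagate_shapes()`) and is
cross-checked against empirical activation sizes in the tests.

Weights come either from a flat binary file (one JSON header line plus
little-endian float32, `write_cnn_weights()`/`read_cnn_weights()`) or from a
seeded He-style random initialization with zero biases. Random-weight
convolutional features are a meaningful baseline: the architecture alone
imposes local, multi-scale, translation-covariant structure, and the package
asserts only that such features beat chance — not that they match features
from a network trained on natural images.

Grayscale sections are replicated to three channels, bilinearly resized to
231 × 231, scaled to [0, 1] (8- or 16-bit inputs) and centered at 0.5
(`preprocess_section()`). Per-gene aggregation is element-wise **max** (or
average) over the per-section tap vectors (`pool_sections()`), which is
invariant to section order and count — asserted by the tests for both
representations.

Computational note: materializing all weights through layer 18 costs roughly
1 GB (the first fully connected layer alone is 36,864 × 3,072), so
`build_extractor(max_layer =)` limits how deep weights are materialized;
`extract_cnn_features()` sets it to the requested tap automatically. Because
weights are generated sequentially per layer from one seeded stream, limiting
the depth does not change the weights of earlier layers.

## Per-structure classification and evaluation

For each structure, an L2-regularized logistic regression
(`train_logistic()`) minimizes

    sum_i log(1 + exp(-y_i (w'x_i + b))) + lambda * ||w||^2

with the bias unpenalized. The penalty is the *squared* L2 norm (the standard
ridge form); `lambda = 1` by default. Optimization is damped Newton with
Armijo backtracking, so the recorded objective trace is monotone by
construction. When the feature dimension exceeds the number of training genes
(the usual case: 10,521- or 147,456-dimensional features, tens of genes), the
representer reparametrization `w = X'a` reduces the Newton system to
(n + 1) dimensions; the tests verify agreement with an independent solver
(`glmnet`) in the overlapping regime.

Genes are split once per evaluation level into 2/3 training and 1/3 test by
`balanced_split()`: random splits are drawn until, in every eligible
structure, the minority/majority class ratio in **both** the training and the
test part reaches a threshold (initially 1/3). After 5,000 failed draws the
threshold is multiplied by 0.8 and sampling repeats; below a floor of 0.01
the most balanced draw seen is returned with a warning. Structures with a
single class overall cannot be balanced; they are excluded from the ratio
check and flagged. Checking the ratio in both parts (not only training)
guards against test sets that are too one-sided to estimate an AUC.

Performance per structure is the area under the ROC curve, computed as the
Mann–Whitney statistic from rank sums with tie handling (`auc_score()`),
verified against the O(n₊·n₋) pairwise count. The per-level summary is the
*unweighted* mean AUC over evaluated structures (`annotate_level()`),
treating each structure as one annotation task regardless of how many genes
it has; structures lacking both classes in either split part are skipped and
reported.

## The synthetic generator

Real curated atlas data cannot ship with a package, so `simulate_dataset()`
generates stacks with known ground truth. It is a *test harness*, not a
tissue model; its defaults are fixed study conditions, not tuning knobs.

* The ontology is laid out as nested axis-aligned rectangles
  (`compute_layout()`): children split the parent rectangle along alternating
  axes, inside a 10% border band kept exclusive to the parent. Each
  structure's *exclusive* in-plane mask is its rectangle minus its children's
  rectangles, so paint for a parent never contaminates a child's ground
  truth.
* Each structure also owns a sagittal range; sibling ranges partition the
  parent's range. A structure is painted only into sections whose position
  falls inside its range. This gives the sagittal-interval averaging of the
  BOW representation a real localization signal to exploit and mirrors the
  fact that anatomical structures appear only in some sections.
* Detection is drawn independently per (gene, structure) with probability
  1 − `undetected_fraction` (default 0.8, reproducing the strong dominance of
  the undetected category in curated data). A detected pair gets uniform
  pattern (full / regional / gradient), intensity and density categories:
  pattern full paints the whole exclusive mask, regional a contiguous half,
  gradient ramps blob amplitude across the rectangle; intensity sets blob
  amplitude (0.15 / 0.30 / 0.50) and density the blob rate (4 / 9 / 18 per
  1,000 masked pixels, Gaussian blobs of σ = 2.5 px).
* Sections are 270 × 360 px (17 per gene by default) with mean background
  0.12 and additive Gaussian pixel noise (sd 0.02), clipped to [0, 1].

What the generator deliberately does **not** emulate: realistic anatomy
(rectangles, not brains), section-to-section registration error, staining
artifacts, cell-scale morphology, or correlated expression across structures.
Conclusions about *absolute* annotation accuracy therefore do not transfer to
real atlas data; the generator supports correctness and recovery claims only.

## Numerical details worth knowing

* **Determinism.** Every stochastic stage takes a seed; internal streams are
  derived per sub-task (`derive_seed()`) and the global RNG state is saved
  and restored, so library calls never perturb user RNG state and results are
  bit-reproducible given a seed.
* **Tie-breaking.** Nearest-centroid assignment breaks ties by lowest
  centroid index; AUC handles score ties via midranks.
* **Tolerances.** Newton stops on a gradient-norm tolerance of 1e−6 (at most
  1,000 iterations); the Newton system is solved with a tiny ridge (1e−10)
  and falls back to the gradient direction if the solve fails.
* **Clamps.** Descriptor components are clamped at 0.2 before renormalizing;
  interval and histogram indices are clamped at their upper boundary so
  maxima land in the last bin.

## Evaluation scale used by this package

The recovery experiments shipped with the package (test suite and
`scripts/acceptance.R`) use 200 genes × 17 sections with 20% detected pairs
for the BOW representation, and 60 genes × 5 sections for the random-weight
CNN representation (forward passes dominate the cost, so the CNN run is
smaller; the claim tested there — above chance by more than three standard
errors — is scale-free). Codebooks in these runs use a 10,000-descriptor pool
with 2 restarts and 25 Lloyd iterations per scale; these are practical
choices for a single-CPU run and are recorded in each run's output.

## Limitations

* Random-weight CNN features are a baseline, not a reproduction of features
  from a trained network; absolute AUCs on synthetic data say nothing about
  relative merits of the two representations on real ISH material.
* The logistic solver targets the dense, small-n regime of this pipeline; it
  is not a general-purpose sparse GLM.
* The forward CNN pass is pure R; it is deliberately simple and verifiable
  rather than fast.
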
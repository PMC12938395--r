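---
title: "Cross-modal imaging-pathology alignment and proxy-based survival prediction"
author: "pathproxy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal imaging-pathology alignment and proxy-based survival prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathproxy)
```

## The problem

Glioblastoma prognosis models built on preoperative MRI alone ignore the
histopathology that only becomes available after surgery. Because the two
modalities are separated in time by the operation itself, they cannot simply
be fused at inference for new patients: a newly imaged patient has no slide.
`pathproxy` implements a retrieval-based answer. During training, paired
patients (MRI volume or imaging feature vector, plus a whole-slide-image
patch-feature set) are embedded into one unit-sphere space by contrastive
alignment. The frozen model then embeds the whole paired cohort into a
library of `(id, e_img, e_path)` records. At inference, an imaging-only
patient's embedding queries the library by cosine similarity; the best
matching pathology embedding serves as a *proxy* pathology representation,
which is concatenated with the imaging feature for binary 12-month
overall-survival classification.

## Model components

**Imaging encoder.** The contract is a convolutional feature extractor
followed by global average pooling over the spatial dimensions. The package
ships a small 3D residual network (two stages, well under 200k parameters)
with seeded random weights, used as a fixed, deterministic feature
extractor; most workflows instead run in *feature-bypass* mode, where a
precomputed imaging feature vector passes through unchanged. We deliberately
do not backpropagate through the 3D convolutions: at desk scale the
convolutional stage acts as a random projection bank and the trainable
imaging pathway is the projection head, which preserves the training
dynamics that matter for alignment while keeping runs tractable on one CPU.

**Patch aggregator.** A slide is a variable-length set of `N` patch feature
vectors of dimension `C`. A learnable CLS token is prepended and the
sequence is processed by a post-norm transformer encoder
(`num_heads = 4`, `depth = 2`, `mlp_ratio = 4`, dropout 0.1 in training
mode); a key padding mask removes padded rows from every attention
computation, so they provably contribute nothing. No positional encodings
are used, making the aggregator a set function — permutation invariance
over valid rows is part of the tested contract. `C` defaults to 64 at desk
scale; 1536 mirrors the width of pathology foundation-model features.

**Projection heads and the objective.** Each modality feature is mapped by
`g(x) = W2 ReLU(LayerNorm(W1 x))` (hidden 256 imaging / 512 pathology by
convention, output `d = 256`, configurable) and L2-normalized. For a batch
of `N` patients the scaled similarity matrix is
`S[i, j] = (e_img[i] . e_path[j]) / tau`, and the symmetric InfoNCE loss is

    L = 1/2 (L_row + L_col)
    L_row = -(1/N) sum_i log( exp(S[i,i]) / sum_j exp(S[i,j]) )

with `L_col` the column-wise analogue. The loss is `ln N` for a constant
matrix, zero iff every diagonal softmax probability is one, and invariant
to transposing `S` while swapping the modality roles; its analytic gradient
`((P_row - I) + (P_col - I)) / (2N)` is verified against finite differences
in the test suite. Softmaxes are computed with max-subtraction
stabilization because `1/tau` reaches 100 at the smallest grid temperature.

**Optimization.** Adam with a cosine-annealed learning rate from 3e-3 to
1e-6, weight decay 1e-5 applied to weight matrices only (normalization
parameters, biases and the CLS token are excluded, the usual practice),
batch size 15 for alignment and 20 for classification, in-batch negatives
only. The temperature defaults to 0.07; a grid
`{0.01, 0.05, 0.07, 0.1, 0.2}` can be searched, scored by validation
Recall@1 — the checkpoint-selection metric throughout (the classification
stage selects by validation AUROC instead). A singleton trailing batch is
skipped: a contrastive batch of one has no negatives.

**Retrieval.** The library stores unit embeddings of both modalities. The
default query mode compares the query imaging embedding directly against
the stored pathology embeddings; a `"paired"` mode (imaging-to-imaging
match, then take the paired pathology record) is also provided, since both
readings of maximum-similarity matching are defensible. For `k > 1` the
proxy is the similarity-weighted mean (weights `max(cos, 0)` normalized,
uniform fallback if all are nonpositive) of the k pathology embeddings,
re-normalized to the unit sphere. Ties break by patient-id order. Exact
scan is both the oracle and the implementation — K is at most a few
hundred.

**Metrics.** Ranks of true matches are pessimistic under ties (equal-
similarity competitors count ahead), so recall never benefits from ties.
AUROC uses the midrank statistic, which handles ties exactly and has a
one-line brute-force oracle; random rankings give Recall@k = k/N and
MRR = H_N/N, identities used as analytic baselines.

## WSI preprocessing operators

Tiling partitions a slide image into non-overlapping square patches
(256 px at full scale), dropping partial border tiles; no border rule is
assumed beyond the floor. Background rejection computes a slide-level Otsu
threshold on the 256-bin luminance histogram (maximizing between-class
variance, ties to the lowest level) and keeps patches whose fraction of
below-threshold (darker-than-glass, i.e. tissue) pixels is at least 0.5.
The per-slide threshold and the 0.5 cutoff are documented defaults — the
cutoff for "dominated by background" is a judgment call, exposed in the
API. Macenko stain normalization uses the conventional constants
`I0 = 255`, OD floor `beta = 0.15`, angular percentile `alpha = 1`, and
adds one intensity level before the log. Concentrations are solved by
nonnegative least squares (closed-form for the two-stain design) because
concentrations are physical quantities; the reference hematoxylin/eosin
basis is shipped and overridable. Tumor-centroid cropping extracts an
80-voxel cube at full scale, shifting the window inward at boundaries
rather than padding.

## The synthetic cohort generator

The generator is the package's study condition, not a demo. Each patient
draws a latent state `z ~ N(0, I_L)` with `L = 4`. The imaging view is
`A z + eps`, `eps ~ N(0, sigma_img^2)`, with `A` drawn once per seed
(512-dimensional by default). Every patch row is `B [z; h(z)] + noise`
with patch noise sd 0.1 and patch counts uniform on 8–32. The mediating
nonlinearity is coordinate-wise, bounded and band-limited:
`h(z) = cos(2 z) - exp(-2)` (centered under standard-normal z). The
survival logit is `w . h(z)` with `w = 1.5 (1, -1, 0.8, -0.8)`,
and survival time is `12 exp(0.25 (logit + logistic noise))` months, so
`P(OS > 12 | z) = plogis(logit)` exactly — the label model is logistic in
closed form, which the label-consistency test exploits. Exactly 12.0
months maps to label 0 (the strictly-greater reading of "more than one
year").

The mediation structure is the point: survival depends only on `h(z)`,
which pathology exposes almost noiselessly and *linearly*, while imaging
carries only the linear view `A z` plus noise — a classifier on imaging
must both denoise `z` and learn the nonlinearity from limited labels,
whereas a retrieved pathology proxy hands the nonlinear features over
precomputed. Two length scales motivate the choices. First, the
least-squares error of latent recovery from imaging is approximately
`sigma_img * sqrt(L / D)`; the default `sigma_img` is set so this error is
an appreciable fraction of the unit latent scale — small enough that
cross-modal retrieval remains accurate, yet large enough that a small
classifier with a few hundred labels cannot fully recover the
pathology-visible nonlinearity from imaging alone (with `sigma_img` well
below 1 the imaging view is an almost clean linear code of `z` and the
proxy is redundant; beyond about 2, retrieval itself degrades and both
arms suffer). Second, `h` varies on the scale `1/2` in latent units —
finer than what the imaging noise resolves, but coarser than the spacing
of a few-hundred-patient library (about `K^(-1/L)` in latent units), so a
*close* retrieved neighbour carries the signal while wide neighbourhood
averages smooth it away. A low-frequency mediator such as plain squaring
fails the first property (it is too easy to learn from imaging), which
suppresses the very mediation the generator exists to exhibit. The
generator does not attempt MRI contrast physics or histology texture; its
fixtures are statistical. Passing tests therefore demonstrate the
*mechanism* (alignment, retrieval, proxy fusion) under a controlled
mediated signal, not performance on real cohorts.

Patients with several slides are out of scope: the generator emits one
patch set per patient, mirroring the unresolved pairing question for
multi-slide patients in real cohorts.

## Desk-scale study conditions

The default end-to-end run (`runConfig()`) generates 600 patients; 400
form the paired alignment/library subset and 200 are treated as
imaging-only survival patients (70/30 train/validation). The split is
deliberately library-heavy: the proxy mechanism depends on library
coverage of the latent space (neighbour distance scales as `K^(-1/L)`),
while the survival label budget is the scarce resource in the scenario the
package emulates. Alignment runs 50
epochs at embedding dimension 64 (hidden 64/128); the survival MLP (one
hidden layer of 32) runs 60 epochs. These sizes keep a full pipeline run
to roughly a minute on one CPU while leaving the contrastive and retrieval
behaviour qualitatively intact (a default pipeline run takes a couple of
minutes on one CPU); the retrieval acceptance checks use the
paired-cohort sizes 38 and 18 with their analytic k/N baselines, and the
trained-retrieval check uses 60 training pairs against 38 held-out
patients at embedding dimension 16 and 30 epochs. The full-scale settings
(embedding 256, C 1536, 100 epochs, 80-voxel crops) remain available
through the same configuration objects.

## Numerical and design choices

- Post-norm transformer layers, matching the standard encoder layout the
  aggregator names; dropout only in training mode, and every tested
  contract is evaluation-mode.
- `nnls2` solves the two-column nonnegative least squares in closed form
  by active-set enumeration, vectorized over pixels; it is checked against
  a generic NNLS solver in the tests.
- A stain estimate on a rank-deficient OD cloud (single-stain patch)
  errors rather than guessing a second vector; the relative
  second-singular-value floor is 1e-3.
- `l2Normalize` raises an error at (near-)zero norm rather than returning
  a NaN direction.
- Master seeds fan out to stage seeds through a fixed integer map, so any
  stage can be reproduced in isolation; all seeds stay below 2^31.
- Weight decay is coupled L2 (added to the gradient before the Adam
  moments), matching the stated L2-regularization reading rather than
  decoupled AdamW.
- The proxy used for fusion is the library's pathology *embedding* (unit
  norm, dimension d); fusing the retrieved patient's raw slide feature
  instead would also be defensible, but the embedding is what the
  maximum-similarity matching returns and keeps the fused dimension
  independent of C.
- "Channel-wise" fusion is flat vector concatenation, imaging block first,
  since the proxy is a vector rather than a feature map.

## Known limitations

- The simulator's latent space is a single smooth Gaussian; it has no
  subtype clusters, no site effects, and no censoring. In such a space the
  similarity-weighted top-k proxy is a kernel-regression estimate, so
  widening k tends to help rather than hurt — the opposite of what sparse,
  heterogeneous real cohorts show, where far neighbours are genuinely
  different patients. The top-k ablation should be read with that in mind.
- The imaging encoder's convolutional stage is not trained; volumetric
  workflows rely on the projection head (and classifier) to adapt random
  convolutional features.
- Retrieval quality is bounded by library coverage: latent regions absent
  from the paired cohort retrieve mismatched proxies, and nothing in the
  package detects that.
- No data augmentation is implemented: augmentation (random flips,
  rotations, crops) belongs to raster/volume training, and the package's
  trainable paths operate on precomputed features, where augmenting is
  off by design.
- No continuous-time survival modelling and no class rebalancing; the
  survival task is a fixed binary 12-month split.
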
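---
title: "Methods: activation extraction and representational similarity in netrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation extraction and representational similarity in netrsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrsa)
```

## The problem and the model of computation

Comparing a neural network's internal representation of a stimulus set with
brain or behavioral data requires three things to be exactly right: the
order in which images enter the network, the identity of the module whose
output is captured, and the layout of the resulting feature matrix. `netrsa`
treats all three as first-class contracts.

A model is a tree of named modules. The root's immediate children are the
*leaves* a user addresses (for the canonical AlexNet: `features`, `avgpool`,
`classifier`); a module address joins names with periods, so `features.10`
is the eleventh entry (0-indexed) of the `features` container — the fifth
convolution, with 256 output feature maps. "Module" deliberately covers
more than trainable layers: non-linearities and pooling steps are
addressable too, and capturing at a `relu` returns the post-activation
value (hook-on-output semantics), which is what one usually wants when
selecting rectified convolutional features.

Given a batch $X \in \mathbb{R}^{B \times C \times H \times W}$, the engine
executes modules in registered order and returns the output
$Z \in \mathbb{R}^{B \times K \times H' \times W'}$ of the addressed module.
Forward rules are implemented from first principles:

* `conv2d`: zero-padded cross-correlation; output spatial size
  $\lfloor (H + 2p - k)/s \rfloor + 1$. Internally evaluated by patch
  extraction (im2col) and one BLAS matrix multiplication per layer, which
  keeps a full AlexNet pass at 224 px around one second on one CPU while
  remaining numerically identical (within $10^{-6}$) to the quadruple-loop
  direct summation the test suite uses as an oracle.
* `maxpool2d`: windowed maximum (ties need no rule); same size formula, no
  padding.
* `adaptive_avgpool2d`: means over the standard bin partition
  $[\lfloor (i-1)H/t \rfloor + 1, \lceil iH/t \rceil]$.
* `linear`: affine map; 4-D inputs are flattened first, mirroring the
  implicit reshape between convolutional and fully-connected stages of
  published recipes.
* `dropout` is the identity (inference mode); `batchnorm2d` applies stored
  statistics $(x-\mu)/\sqrt{\sigma^2+\varepsilon}\cdot\gamma+\beta$, which
  default to the identity-like $\mu=0,\sigma^2=1,\gamma=1,\beta=0$ under
  random initialization.

### Random weights

Architecture-only comparisons (what does the wiring contribute, before any
learning?) need reproducible random weights. No standard exists for the
initialization distribution in this setting, so the package fixes one:
uniform on $(-1/\sqrt{\text{fan}_{in}}, +1/\sqrt{\text{fan}_{in}})$, the
conventional scaling that keeps activation variance roughly constant across
depth. Draws come from a stream keyed by (global seed, module path), so a
module's weights do not depend on tree traversal order, and two builds with
the same seed are identical to the last bit. Pretrained weights are only
ever read from a local HDF5 archive (one group per module path); nothing is
downloaded.

## Dataset ordering

Alphabetic sorting is locale- and OS-dependent, which has caused real
row-misalignment bugs in this kind of pipeline. `netrsa` removes the
ambiguity instead of emulating any one OS: relative paths are sorted in
byte-wise codepoint order (radix sort; digits < uppercase < lowercase), so
`10.tif < A.jpg < b.png` everywhere, and paths are not lower-cased first. A
user list overrides sorting entirely and is honored verbatim. Whatever the
source of the order, `file_names.txt` (UTF-8, LF) records it line-by-line,
and row $i$ of every feature matrix corresponds to line $i$; re-scanning
with that file as the explicit list reproduces the dataset exactly, which
the tests assert as an involution.

Class labels come from first-level sub-folder names, with indices assigned
by sorted label order from 0; flat directories get label 0 throughout. The
target vector is always attached to extraction output — saving or ignoring
it is the caller's choice.

### Input transform

The default transform resizes the shorter side to 256 (bilinear,
half-pixel-centre convention), centre-crops to 224, and normalizes with the
canonical ImageNet constants (mean 0.485/0.456/0.406, sd 0.229/0.224/0.225)
— the preprocessing contract of ImageNet-trained models. Every constant is
user-configurable, and each registered architecture carries its own default
(`toynet` uses 8 px, mean/sd 0.5). Grayscale images are replicated to three
channels, alpha channels dropped, 8-bit values scaled to $[0,1]$. EPS
files are accepted by the directory scanner (the extension set is
`.eps .jpg .jpeg .png .PNG .tif .tiff`) but rejected at decode time with a
clear error, since no rasterizer is bundled.

The `layout` option selects where the channel axis sits in batches
(`channels_first`, $B{\times}C{\times}H{\times}W$, the default; or
`channels_last`, $B{\times}H{\times}W{\times}C$). It exists because both
conventions are common in practice; the engine permutes `channels_last`
input internally and results are identical either way (tested).

## Flattening and persistence

Flattening $Z \in \mathbb{R}^{B\times K\times H\times W}$ to
$\mathbb{R}^{B \times KHW}$ requires pinning an element order; the package
fixes channel-major (channel, then height, then width — width fastest),
records `flatten_order` in saved metadata, and provides the exact inverse
`unflatten_activations()`. `flatten_acts` has no default on purpose: 2-D is
right for regression/RSA against brain or behavior, 4-D for feature-map
inspection, and silently choosing either would be a footgun.

Four storage formats are supported (`npy`, `txt`, `mat`, `hdf5`). 4-D
tensors keep their shape in the three binary formats; text is restricted to
2-D, with `tensor_to_slices()`/`slices_to_tensor()` as the exact-inverse
escape hatch. Numeric layout conventions: `txt` is one row per line,
space-separated, scientific notation with 8 significant digits (round trips
within $10^{-6}$; binary formats are bit-exact); the MAT variable and HDF5
dataset are both named `features`, targets in `targets`. NPY and MAT-v5
writers/readers are implemented in-package for the double-precision subset
emitted here and are byte-compatible with the reference readers of those
formats. Large flattened matrices can be saved in $k$ contiguous row splits
(default $k = 10$, multiples of 10 recommended when memory is tight): the
first $N \bmod k$ parts get $\lceil N/k \rceil$ rows, the rest
$\lfloor N/k \rfloor$, files are numbered `features_<i>_of_<k>`, and
`merge_features()` refuses gaps or mixed $k$ rather than guessing.
Re-extraction into a non-empty output directory overwrites and logs; the
alternative (refusing) would break iterative workflows for no integrity
gain, since the order record is rewritten atomically with the features.

## Representational similarity

An RDM is the $N \times N$ matrix of pairwise dissimilarities between
condition representations (rows, never features). Metrics: euclidean
$\lVert x_i-x_j\rVert_2$ (unbounded); correlation $1-r_{ij}$ and cosine
$1-\cos\theta_{ij}$ (both bounded by 2, attained at perfect
anti-correlation/anti-alignment); and a gaussian radial basis function
$1-\exp(-d_{ij}^2/2\sigma^2)$ on euclidean distances. The RBF form and
bandwidth are design choices of this package: this form is bounded in
$[0,1)$, monotone in distance, and the median-heuristic
$\sigma$ (median off-diagonal euclidean distance) makes it parameter-free
while remaining overridable. Symmetry is enforced by averaging with the
transpose (removing $10^{-16}$-scale asymmetric rounding), the diagonal is
set to 0, and sub-$10^{-12}$ negative rounding residues are clamped to 0.
Constant rows make the correlation distance undefined and raise an error
naming the offending rows, rather than propagating `NaN`s.

Two RDMs are compared by correlating their strict upper triangles
(diagonal excluded): Pearson by default, Spearman (average ranks, then
Pearson) when dissimilarities should only be trusted ordinally. At least 3
conditions are required — below that the triangle has fewer than 3 entries
and a correlation is meaningless.

Heat maps are written at 200 dpi by default (high enough to survive jpg
compression); `.png` (lossless) is the default format, `.jpg` accepted,
anything else rejected. `reorder_rdm()` makes block structure visible:
average-linkage agglomerative clustering on the RDM as a precomputed
dissimilarity, cut at $k$ clusters, clusters ordered by ascending
within-cluster mean dissimilarity (singletons count 0), original order kept
within clusters. Average linkage is the recorded choice here because it
operates directly on arbitrary dissimilarities without requiring euclidean
embeddability (ward/centroid would). The permutation and labels are
returned, and the reordered matrix is exactly $PRP^\top$.

## Synthetic data

The generators exist so the whole pipeline is testable without downloads,
and they define the package's study conditions.

`generate_image_set()` plants class structure in images: each class gets a
smooth base pattern per channel (a mixture of 4 low-frequency cosine
gratings, frequencies 0.5–3 cycles/image, random phase), and each image
adds i.i.d. pixel noise (sd 0.08) before clamping to $[0,1]$. Low-frequency
structure, not white noise, is what makes convolution and pooling layers
produce non-degenerate, class-separable activations. Everything is keyed by
(seed, class, image), so the same call is byte-identical twice over.

`generate_structured_features()` plants cluster geometry in feature space:
centroids drawn with per-coordinate spread `between_sd` (default 2.0),
rows = centroid + isotropic noise `within_sd` (default 0.1; dimensionality
20, 2 clusters of 5 by default). The returned "true" RDM is the euclidean
RDM of the noiseless rows — zero within clusters, centroid distances
between — i.e. the block structure the noisy RDM converges to as
`within_sd` $\to 0$.

What these fixtures do **not** emulate: natural-image statistics (1/f
spectra, objects, occlusion), correlated feature noise, or any trained
representation. Passing tests therefore demonstrate the *mechanics* —
ordering, capture, shapes, metric properties, recovery of planted structure
at generous separation — not that any particular network explains any
particular brain. Claims of the latter kind require real stimuli, real
recordings and pretrained weights, all out of scope here.

## Problem sizes and numerical choices

The test suite runs on deliberately small problems: 8–32 px synthetic
images, `toynet` for all pipeline properties, 50 random conv cases up to
$4{\times}4{\times}16{\times}16$ against the brute-force oracle, 100 random
matrices for the metric-bound sweep, 20 replicate pairs for the
RDM-stability simulation, and a single 224 px AlexNet forward pass for the
channel-count check. These sizes were chosen as the smallest that exercise
every code path and invariant non-trivially; the whole suite completes in
well under a minute.

Tolerances reflect arithmetic reality rather than aspiration: bit-exact
where the computation is deterministic and order-stable (binary format
round trips, seeded weight draws, slicing inverses), $10^{-6}$ where
BLAS-reassociated summation meets a naive loop (conv oracle, batch-size
invariance), $10^{-10}$ for pairwise-distance algebra, $10^{-8}$ for the
affine-invariance of the correlation distance.

Known limitations: no training or gradients; no GPU (the `device = "gpu"`
option is accepted and falls back to CPU with a warning, since execution
device must never change results); registry limited to `alexnet` and
`toynet` plus user-supplied recipe files — adapters for framework model
zoos are a documented contract (module listing + activation capture at a
path), not shipped code; `.eps` decoding unavailable; MAT/NPY support
restricted to the double-precision subset the package itself writes.
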
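# netrsa

Layer-activation extraction and representational similarity analysis for R.

Researchers in cognitive science and computational neuroscience routinely
compare the internal representations of deep neural networks with brain
recordings and behavioral judgments. The error-prone part is rarely the
statistics — it is getting from a folder of stimulus images to a feature
matrix whose row *i* provably corresponds to image *i*, extracted at a
well-defined layer of a well-defined network. `netrsa` streamlines exactly
that pipeline, end to end, in R:

* **Ordered image datasets.** A directory of images (flat, or one level of
  class sub-folders) becomes a deterministically ordered dataset: byte-wise
  codepoint order of the relative path on every platform, or exactly the
  order of a user-supplied file list. The extraction order is always written
  to `file_names.txt` beside the features.
* **A deterministic inference engine.** Models are trees of named modules
  (`conv2d`, `relu`, `maxpool2d`, `adaptive_avgpool2d`, `linear`, `dropout`,
  `batchnorm2d`, `flatten`), addressed by period-joined paths such as
  `features.10`. The registry ships the canonical AlexNet layout (five
  convolutions, three linear maps; leaves `features`, `avgpool`,
  `classifier`) and a small `toynet` for fast experiments; custom recipes
  load from flat text files, and weights from local HDF5 archives. Random
  initialization is uniform on (−1/√fan_in, +1/√fan_in), keyed by
  (seed, module path), so every run is reproducible.
* **Activation capture and flattening.** Batches `X ∈ R^{B×C×H×W}` run
  forward to the chosen module; its output `Z ∈ R^{B×K×H×W}` is optionally
  flattened to one `K·H·W` vector per image (channel-major order) and
  concatenated into the `N × KHW` feature matrix, with the `N × 1` integer
  target vector attached.
* **Persistence.** Features save and reload in `npy`, `txt`, `mat` and
  `hdf5`; 4-D tensors keep their shape in the three binary formats (or are
  sliced into per-image `K × HW` matrices for text). Row-wise `k`-way
  splitting (default `k = 10`) with lossless merge handles matrices too
  large to write in one piece.
* **RSA.** Representational dissimilarity matrices under four metrics —
  euclidean `‖x_i − x_j‖₂`, correlation `1 − r`, cosine
  `1 − cosθ`, and a gaussian RBF `1 − exp(−d²/2σ²)` with median-heuristic
  bandwidth — plus upper-triangle Pearson/Spearman comparison of two RDMs,
  200-dpi heat-map plots, and average-linkage cluster reordering.

## Worked example

Generate a small synthetic stimulus set (three classes with distinct smooth
patterns), extract pooled convolutional features, and inspect the
representational geometry:

```r
library(netrsa)

generate_image_set("demo_imgs", n_classes = 3, n_per_class = 4,
                   size = 32, seed = 0)

model <- build_architecture("toynet", pretrained = FALSE, seed = 0)
cat(enumerate_modules(model), sep = "\n")
#> features.0: conv2d(in=3, out=4, kernel=3, stride=1, padding=1)
#> features.1: relu()
#> features.2: maxpool2d(kernel=2, stride=2)
#> classifier.0: flatten()
#> classifier.1: linear(in=64, out=8)
#> classifier.2: relu()
#> classifier.3: linear(in=8, out=3)

ds <- scan_images("demo_imgs",
                  transform = transform_spec(resize = 8, crop = 8,
                                             mean = rep(0.5, 3), std = rep(0.5, 3)))
ds
#> <image_dataset> 12 images under 'demo_imgs' (3 classes)

fm <- extract_features(model, batch_iterator(ds, 4), "features.2",
                       flatten_acts = TRUE, row_names = ds$records$path)
fm
#> <feature_matrix> 12 x 64 from module 'features.2' (flattened from 4x4x4)

rdm <- compute_rdm(fm$values, method = "correlation")
same <- outer(fm$targets, fm$targets, "==")
mean(rdm[upper.tri(rdm) & same])    # images of the same class look alike
#> 0.044
mean(rdm[upper.tri(rdm) & !same])   # different classes are far apart
#> 0.676
```

Within-class correlation distances (0.044) are an order of magnitude below
between-class distances (0.676): the random-weight network already separates
the planted image classes, purely through its architecture. Reordering the
RDM by unsupervised clustering (`reorder_rdm(rdm, 3)`) recovers the three
classes as contiguous 4/4/4 blocks, and `plot_rdm(rdm, "rdm.png")` writes
the heat map.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/netrsa.R extract --root demo_imgs --model toynet \
    --module features.2 --flatten --format npy --out out/
Rscript inst/cli/netrsa.R rdm --features out/ --method correlation --out out/
```

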
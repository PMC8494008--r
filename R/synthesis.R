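# Seeded fixture generators: synthetic image sets with class structure and
# feature matrices with planted representational geometry. All generators
# are pure functions of their seed.

# Smooth random field on [0,1]^2: a mixture of low-frequency cosine gratings.
# White noise would give pooling and convolution layers degenerate structure;
# gratings give every class a distinct, spatially coherent appearance.
.cosine_field <- function(size, n_components = 4L) {
  gx <- matrix(seq(0, 1, length.out = size), size, size)
  gy <- t(gx)
  field <- matrix(0, size, size)
  for (i in seq_len(n_components)) {
    fx <- runif(1, 0.5, 3); fy <- runif(1, 0.5, 3)
    phase <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.5, 1)
    field <- field + amp * cos(2 * pi * (fx * gx + fy * gy) + phase)
  }
  field <- field - min(field)
  field / max(field)
}

#' Generate a synthetic class-structured image set
#'
#' Creates `out_root/class_<c>/img_<c>_<i>.<fmt>`. All images of a class
#' share a class-specific smooth base pattern (a seeded low-frequency cosine
#' mixture per channel) plus per-image seeded noise, so within-class pixel
#' correlation exceeds between-class correlation. Deterministic: the same
#' arguments produce byte-identical files.
#'
#' @param out_root output directory (created if needed).
#' @param n_classes number of class sub-folders.
#' @param n_per_class images per class.
#' @param size image side length in pixels (`>= 8`).
#' @param seed non-negative integer seed.
#' @param fmt `"png"`, `"jpg"` or `"tif"`.
#' @param noise_sd pixel noise standard deviation around the class pattern.
#' @return `out_root`, invisibly.
#' @export
generate_image_set <- function(out_root, n_classes = 3L, n_per_class = 4L,
                               size = 64L, seed = 0L, fmt = c("png", "jpg", "tif"),
                               noise_sd = 0.08) {
  fmt <- match.arg(fmt)
  if (size < 8L) nr_error("netrsa_parameter_error", "size must be at least 8 pixels")
  if (!dir.exists(out_root) && !dir.create(out_root, recursive = TRUE, showWarnings = FALSE)) {
    nr_error("netrsa_io_error", sprintf("cannot create image root '%s'", out_root))
  }
  for (c_idx in seq_len(n_classes)) {
    cls_dir <- file.path(out_root, sprintf("class_%d", c_idx))
    dir.create(cls_dir, showWarnings = FALSE)
    base <- with_local_seed(seed, sprintf("class_%d", c_idx), {
      array(c(.cosine_field(size), .cosine_field(size), .cosine_field(size)),
            dim = c(size, size, 3))
    })
    for (i in seq_len(n_per_class)) {
      img <- with_local_seed(seed, sprintf("class_%d/img_%d", c_idx, i), {
        pmin(pmax(base + array(rnorm(size * size * 3, sd = noise_sd),
                               dim = c(size, size, 3)), 0), 1)
      })
      path <- file.path(cls_dir, sprintf("img_%d_%d.%s", c_idx, i, fmt))
      switch(fmt,
        png = png::writePNG(img, path),
        jpg = jpeg::writeJPEG(img, path, quality = 0.95),
        tif = tiff::writeTIFF(img, path)
      )
    }
  }
  invisible(out_root)
}

#' Generate a feature matrix with planted cluster geometry
#'
#' Draws `n_clusters` centroids with per-coordinate spread `between_sd` and
#' places `n_per_cluster` rows around each centroid with isotropic noise
#' `within_sd`. The planted geometry is returned as the euclidean RDM of the
#' noiseless rows (each row replaced by its centroid): zero within clusters,
#' centroid distances between — the block structure the noisy RDM approaches
#' as `within_sd` goes to 0.
#'
#' @param n_clusters number of planted clusters.
#' @param n_per_cluster rows per cluster.
#' @param dim feature dimensionality.
#' @param within_sd within-cluster noise standard deviation.
#' @param between_sd centroid spread; must exceed `within_sd`.
#' @param seed non-negative integer seed.
#' @return list with `features` (`N x dim` matrix), `labels` (integer, 1-based
#'   cluster of each row) and `true_rdm` (the planted block RDM).
#' @export
generate_structured_features <- function(n_clusters = 2L, n_per_cluster = 5L,
                                         dim = 20L, within_sd = 0.1,
                                         between_sd = 2.0, seed = 1L) {
  if (n_clusters < 1L || n_per_cluster < 1L || dim < 1L) {
    nr_error("netrsa_parameter_error", "cluster counts and dim must be positive")
  }
  if (between_sd <= within_sd) {
    nr_error("netrsa_parameter_error", "between_sd must exceed within_sd")
  }
  centroids <- with_local_seed(seed, "centroids", {
    matrix(rnorm(n_clusters * dim, sd = between_sd), nrow = n_clusters)
  })
  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  noise <- with_local_seed(seed, "noise", {
    matrix(rnorm(length(labels) * dim, sd = within_sd), nrow = length(labels))
  })
  features <- centroids[labels, , drop = FALSE] + noise
  true_rdm <- compute_rdm(centroids[labels, , drop = FALSE], method = "euclidean")
  list(features = features, labels = labels, true_rdm = true_rdm)
}
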
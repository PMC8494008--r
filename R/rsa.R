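# Representational similarity analysis: RDM construction under four
# dissimilarity metrics, upper-triangle comparison of two RDMs, heat-map
# plotting, and cluster-based reordering.

.RDM_METRICS <- c("euclidean", "correlation", "cosine", "gaussian")

#' Compute a representational dissimilarity matrix
#'
#' Dissimilarities are computed between conditions (rows), not features.
#' Metrics:
#' \describe{
#'   \item{euclidean}{`||x_i - x_j||_2`; no theoretical upper limit.}
#'   \item{correlation}{`1 - r(x_i, x_j)` (Pearson across the D features);
#'     bounded by 2.}
#'   \item{cosine}{`1 - x_i.x_j / (||x_i|| ||x_j||)`; bounded by 2.}
#'   \item{gaussian}{radial basis function on pairwise euclidean distances,
#'     `1 - exp(-d^2 / (2 sigma^2))`, with `sigma` defaulting to the median
#'     pairwise euclidean distance (entries in `[0, 1)`).}
#' }
#' Equivalent representations score close to 0.
#'
#' @param features `N x D` numeric matrix or [feature_matrix()] (`N >= 2`).
#' @param method one of `"euclidean"`, `"correlation"`, `"cosine"`,
#'   `"gaussian"`.
#' @param sigma RBF bandwidth for `method = "gaussian"`; `NULL` for the
#'   median heuristic.
#' @return an `rdm` object: a symmetric `N x N` matrix with zero diagonal and
#'   attributes `metric` and `conditions`.
#' @export
compute_rdm <- function(features, method = c("euclidean", "correlation",
                                             "cosine", "gaussian"),
                        sigma = NULL) {
  method <- match.arg(method)
  conditions <- if (inherits(features, "feature_matrix")) features$row_names else rownames(features)
  x <- .values_of(features)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) nr_error("netrsa_input_error", "an RDM needs at least 2 conditions (rows)")
  if (method == "correlation") {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      nr_error("netrsa_undefined_correlation_error",
               sprintf("correlation distance undefined for constant row(s): %s",
                       paste(which(sds == 0), collapse = ", ")))
    }
  }
  values <- switch(method,
    euclidean = as.matrix(dist(x, method = "euclidean")),
    correlation = 1 - stats::cor(t(x)),
    cosine = {
      norms <- sqrt(rowSums(x^2))
      if (any(norms == 0)) {
        nr_error("netrsa_input_error",
                 sprintf("cosine distance undefined for all-zero row(s): %s",
                         paste(which(norms == 0), collapse = ", ")))
      }
      1 - tcrossprod(x / norms)
    },
    gaussian = {
      d <- as.matrix(dist(x, method = "euclidean"))
      if (is.null(sigma)) sigma <- median(d[upper.tri(d)])
      if (!is.finite(sigma) || sigma <= 0) {
        nr_error("netrsa_input_error", "gaussian RDM needs a positive bandwidth")
      }
      1 - exp(-d^2 / (2 * sigma^2))
    }
  )
  values <- (values + t(values)) / 2   # kill asymmetric rounding noise
  values[values < 0 & values > -1e-12] <- 0
  diag(values) <- 0
  dimnames(values) <- NULL
  structure(values, class = c("rdm", "matrix"),
            metric = method,
            conditions = conditions %||% as.character(seq_len(n) - 1L))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d, metric = %s\n", nrow(x), ncol(x), attr(x, "metric")))
  invisible(x)
}

#' Strict upper-triangle entries of a square matrix
#'
#' @param m square matrix.
#' @return numeric vector (column-major order, diagonal excluded).
#' @export
upper_triangle <- function(m) m[upper.tri(m)]

#' Correlate the upper triangles of two RDMs
#'
#' Vectorizes the strictly-above-diagonal entries of both RDMs and
#' correlates them. Pearson is the default; choose Spearman (average-rank
#' transform, then Pearson) when the dissimilarities are not assumed to be
#' on a ratio scale.
#'
#' @param rdm_a,rdm_b square matrices of equal size (`N >= 3`).
#' @param correlation `"pearson"` or `"spearman"`.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
correlate_rdms <- function(rdm_a, rdm_b, correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  a <- unclass(as.matrix(rdm_a)); b <- unclass(as.matrix(rdm_b))
  if (!identical(dim(a), dim(b))) {
    nr_error("netrsa_input_error",
             sprintf("RDM shapes differ: %s vs %s",
                     paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  if (nrow(a) < 3L) {
    nr_error("netrsa_input_error", "RDM comparison needs at least 3 conditions")
  }
  ua <- upper_triangle(a); ub <- upper_triangle(b)
  if (correlation == "spearman") {
    ua <- rank(ua, ties.method = "average")
    ub <- rank(ub, ties.method = "average")
  }
  if (stats::sd(ua) == 0 || stats::sd(ub) == 0) {
    nr_error("netrsa_undefined_correlation_error",
             "upper triangle has zero variance; correlation undefined")
  }
  stats::cor(ua, ub)
}

#' Plot an RDM heat map to disk
#'
#' Writes a heat map of the dissimilarity matrix. `.png` (lossless) is the
#' default; `.jpg` is accepted but lossy. The resolution metadata of the
#' written file records the dpi (default 200, chosen for high resolution
#' even under jpg compression).
#'
#' @param rdm an `rdm` object or square matrix.
#' @param out_path output file path (extension replaced by `format`), or a
#'   directory, in which case `rdm.<format>` is written there.
#' @param format `".png"` or `".jpg"`.
#' @param dpi resolution in dots per inch.
#' @param size figure size in inches.
#' @return the written file path, invisibly.
#' @export
plot_rdm <- function(rdm, out_path, format = ".png", dpi = 200, size = 5) {
  if (!format %in% c(".png", ".jpg")) {
    nr_error("netrsa_format_error",
             sprintf("unknown plot format '%s': must be '.png' or '.jpg'", format))
  }
  m <- unclass(as.matrix(rdm))
  if (dir.exists(out_path)) {
    out_path <- file.path(out_path, paste0("rdm", format))
  } else {
    out_path <- paste0(tools::file_path_sans_ext(out_path), sub("^\\.", ".", format))
  }
  open_dev <- if (format == ".png") grDevices::png else grDevices::jpeg
  open_dev(out_path, width = size, height = size, units = "in", res = dpi)
  on.exit(grDevices::dev.off())
  n <- nrow(m)
  graphics::par(mar = c(2.5, 2.5, 2, 4))
  # flip rows so condition 1 sits in the top-left corner
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("RDM (%s)", attr(rdm, "metric") %||% "dissimilarity"))
  graphics::box()
  at <- pretty(seq_len(n)); at <- at[at >= 1 & at <= n]
  graphics::axis(1, at = at, cex.axis = 0.8)
  graphics::axis(2, at = n + 1 - at, labels = at, cex.axis = 0.8, las = 1)
  # simple colour key
  rng <- range(m)
  key_y <- seq(1, n, length.out = 64)
  graphics::rasterImage(grDevices::as.raster(rev(grDevices::hcl.colors(64, "viridis"))),
                        n + 0.5 + n * 0.03, 1, n + 0.5 + n * 0.07, n, xpd = TRUE)
  graphics::text(n + 0.5 + n * 0.09, c(1, n), labels = signif(c(rng[2], rng[1]), 3),
                 xpd = TRUE, cex = 0.7, adj = 0)
  invisible(out_path)
}

#' Reorder an RDM by unsupervised clustering
#'
#' Runs average-linkage agglomerative clustering on the RDM taken as a
#' precomputed dissimilarity, cuts the tree at `n_clusters`, and permutes
#' rows and columns so clusters are contiguous. Clusters are ordered by
#' ascending within-cluster mean dissimilarity (singletons count as 0);
#' the original order is kept within each cluster. The reordered RDM is
#' `P R P'` for the returned permutation.
#'
#' @param rdm an `rdm` object or symmetric dissimilarity matrix.
#' @param n_clusters number of clusters, `2 <= n_clusters <= N`.
#' @return list with `rdm` (reordered, same class/attributes), `permutation`
#'   (integer vector: new order of the original indices), and `clusters`
#'   (integer cluster labels in original order, renumbered by output
#'   position).
#' @export
reorder_rdm <- function(rdm, n_clusters) {
  m <- unclass(as.matrix(rdm))
  n <- nrow(m)
  if (!is_count(n_clusters, min = 2L) || n_clusters > n) {
    nr_error("netrsa_range_error",
             sprintf("n_clusters must be an integer in [2, %d]", n))
  }
  hc <- hclust(as.dist(m), method = "average")
  labels <- cutree(hc, k = n_clusters)
  within_mean <- vapply(seq_len(n_clusters), function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2L) return(0)
    sub <- m[idx, idx]
    mean(sub[upper.tri(sub)])
  }, 0)
  cluster_order <- order(within_mean)
  perm <- unlist(lapply(cluster_order, function(k) which(labels == k)), use.names = FALSE)
  out <- m[perm, perm]
  attributes(out) <- c(attributes(out),
                       attributes(rdm)[setdiff(names(attributes(rdm)), c("dim", "dimnames"))])
  conds <- attr(rdm, "conditions")
  if (!is.null(conds)) attr(out, "conditions") <- conds[perm]
  relabel <- match(labels, cluster_order)
  list(rdm = out, permutation = perm, clusters = relabel,
       method = "agglomerative_average_linkage")
}
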
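test_that("all four metrics give symmetric, zero-diagonal, non-negative RDMs", {
  set.seed(1)
  x <- matrix(rnorm(6 * 10), 6, 10)
  for (m in c("euclidean", "correlation", "cosine", "gaussian")) {
    rdm <- compute_rdm(x, m)
    expect_identical(dim(rdm), c(6L, 6L))
    expect_lt(max(abs(rdm - t(rdm))), 1e-10)
    expect_lt(max(abs(diag(rdm))), 1e-10)
    expect_true(all(rdm >= 0), info = m)
    expect_equal(attr(rdm, "metric"), m)
  }
})

test_that("identical rows score 0 and a negated row attains the bound of 2", {
  base <- c(1, 2, 3, 5, 4)
  dup <- rbind(base, base, c(2, 1, 0, 7, 3))
  for (m in c("euclidean", "correlation", "cosine", "gaussian")) {
    rdm <- compute_rdm(dup, m)
    expect_lt(abs(rdm[1, 2]), 1e-10)
  }
  flip <- rbind(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(compute_rdm(flip, "correlation")[1, 2], 2)
  expect_equal(compute_rdm(flip, "cosine")[1, 2], 2)
})

test_that("euclidean matches hand values and the double-loop oracle", {
  tri <- rbind(c(0, 0), c(3, 4))
  expect_equal(compute_rdm(tri, "euclidean")[1, 2], 5)
  set.seed(2)
  x <- matrix(rnorm(6 * 10), 6, 10)
  expect_lt(max(abs(compute_rdm(x, "euclidean") - naive_euclidean_rdm(x))), 1e-10)
})

test_that("correlation/cosine stay bounded by 2 over 100 random matrices; euclidean is not", {
  worst <- 0
  for (seed in 1:100) {
    set.seed(seed)
    x <- matrix(rnorm(5 * 8), 5, 8)
    worst <- max(worst,
                 max(compute_rdm(x, "correlation")),
                 max(compute_rdm(x, "cosine")))
  }
  expect_lte(worst, 2)
  set.seed(0)
  scaled <- matrix(rnorm(4 * 6), 4, 6) * 100
  expect_gt(max(compute_rdm(scaled, "euclidean")), 2)
})

test_that("gaussian entries lie in [0, 1) and degenerate inputs error clearly", {
  set.seed(3)
  x <- matrix(rnorm(8 * 5), 8, 5)
  g <- compute_rdm(x, "gaussian")
  expect_true(all(g >= 0 & g < 1))
  err <- expect_error(compute_rdm(rbind(rep(1, 4), rnorm(4)), "correlation"),
                      class = "netrsa_undefined_correlation_error")
  expect_match(conditionMessage(err), "1")
  expect_error(compute_rdm(matrix(1, 1, 4), "euclidean"), class = "netrsa_input_error")
})

test_that("correlation distance is invariant to positive affine row transforms", {
  set.seed(4)
  x <- matrix(rnorm(6 * 12), 6, 12)
  a <- runif(6, 0.5, 3); b <- rnorm(6)
  y <- x * a + b                     # row-wise recycling: rows scaled/shifted
  expect_lt(max(abs(compute_rdm(x, "correlation") - compute_rdm(y, "correlation"))), 1e-8)
})

test_that("correlate_rdms matches hand-computed Pearson/Spearman on upper triangles", {
  mk <- function(v) { m <- matrix(0, 3, 3); m[upper.tri(m)] <- v; m + t(m) }
  expect_equal(correlate_rdms(mk(c(1, 2, 3)), mk(c(3, 2, 1))), -1)
  expect_equal(correlate_rdms(mk(c(1, 2, 3)), mk(c(3, 2, 1)), "spearman"), -1)

  r_p <- correlate_rdms(mk(c(1, 2, 4)), mk(c(1, 2, 3)))
  expect_equal(correlate_rdms(mk(c(1, 2, 4)), mk(c(1, 2, 3)), "spearman"), 1)
  expect_lt(r_p, 1)
  expect_equal(r_p, stats::cor(c(1, 2, 4), c(1, 2, 3)))

  set.seed(5)
  r <- compute_rdm(matrix(rnorm(5 * 7), 5, 7), "euclidean")
  expect_equal(correlate_rdms(r, r), 1)

  # spearman is invariant under strictly increasing transforms of one RDM
  expect_equal(correlate_rdms(r, exp(unclass(r)), "spearman"), 1)

  expect_error(correlate_rdms(r, matrix(0, 4, 4)), class = "netrsa_input_error")
  expect_error(correlate_rdms(matrix(0, 2, 2), matrix(0, 2, 2)),
               class = "netrsa_input_error")
  expect_error(correlate_rdms(mk(c(1, 1, 1)), mk(c(1, 2, 3))),
               class = "netrsa_undefined_correlation_error")
})

test_that("plot_rdm writes png/jpg with the requested dpi and rejects others", {
  set.seed(6)
  rdm <- compute_rdm(matrix(rnorm(10 * 6), 10, 6), "correlation")
  out <- withr::local_tempdir()
  p <- plot_rdm(rdm, file.path(out, "r.png"))
  expect_true(file.exists(p))
  info <- attr(png::readPNG(p, info = TRUE), "info")
  expect_equal(unname(info$dpi), c(200, 200), tolerance = 0.51)

  pj <- plot_rdm(rdm, file.path(out, "r2.jpg"), format = ".jpg")
  expect_true(file.exists(pj))
  expect_gt(file.info(pj)$size, 0)

  expect_error(plot_rdm(rdm, file.path(out, "r3.bmp"), format = ".bmp"),
               class = "netrsa_format_error")
})

test_that("reorder_rdm recovers a planted two-block partition and conserves entries", {
  # two blocks interleaved: odd indices one block, even the other
  n <- 8
  labels <- rep(c(1, 2), length.out = n)
  m <- matrix(0.9, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j]) m[i, j] <- 0.1
  }
  diag(m) <- 0
  res <- reorder_rdm(m, 2)
  got_labels <- labels[res$permutation]
  expect_equal(length(unique(got_labels[1:4])), 1L)
  expect_equal(length(unique(got_labels[5:8])), 1L)
  expect_equal(res$rdm, m[res$permutation, res$permutation], ignore_attr = TRUE)
  expect_equal(sort(as.numeric(res$rdm)), sort(as.numeric(m)))

  # n_clusters = N preserves the multiset of entries
  set.seed(7)
  r <- compute_rdm(matrix(rnorm(5 * 6), 5, 6), "euclidean")
  res_n <- reorder_rdm(r, 5)
  expect_equal(sort(as.numeric(res_n$rdm)), sort(as.numeric(unclass(r))))
  expect_error(reorder_rdm(r, 1), class = "netrsa_range_error")
  expect_error(reorder_rdm(r, 6), class = "netrsa_range_error")
})
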
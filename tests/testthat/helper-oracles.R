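# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals.

# Direct-summation cross-correlation: quadruple loop over output positions
# and kernel taps.
naive_conv2d <- function(x, w, b, stride, padding) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  K <- dim(w)[1]; k <- dim(w)[3]
  Ho <- (H + 2 * padding - k) %/% stride + 1
  Wo <- (W + 2 * padding - k) %/% stride + 1
  xp <- array(0, c(B, C, H + 2 * padding, W + 2 * padding))
  xp[, , padding + seq_len(H), padding + seq_len(W)] <- x
  out <- array(0, c(B, K, Ho, Wo))
  for (bi in seq_len(B)) for (ki in seq_len(K)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- b[ki]
    for (ci in seq_len(C)) for (di in seq_len(k)) for (dj in seq_len(k)) {
      acc <- acc + xp[bi, ci, (i - 1) * stride + di, (j - 1) * stride + dj] * w[ki, ci, di, dj]
    }
    out[bi, ki, i, j] <- acc
  }
  out
}

# Pairwise euclidean distances by explicit double loop.
naive_euclidean_rdm <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  }
  out
}

# Random conv2d node plus compatible input for property tests.
random_conv_case <- function(seed) {
  set.seed(seed)
  C <- sample(1:4, 1); K <- sample(1:4, 1)
  k <- sample(1:3, 1); s <- sample(1:2, 1); p <- sample(0:1, 1)
  H <- sample(seq(max(k - 2 * p, 1), 16), 1) + 2 * p
  W <- sample(seq(max(k - 2 * p, 1), 16), 1) + 2 * p
  B <- sample(1:4, 1)
  list(
    x = array(rnorm(B * C * H * W), c(B, C, H, W)),
    node = module_node("conv", "conv2d",
      params = list(in_channels = C, out_channels = K, kernel = k,
                    stride = s, padding = p),
      weights = list(weight = array(rnorm(K * C * k * k), c(K, C, k, k)),
                     bias = rnorm(K))),
    stride = s, padding = p
  )
}

# A ready-made image root with class sub-folders, rebuilt per call.
make_image_root <- function(dir, n_classes = 3, n_per_class = 2, size = 16,
                            seed = 0, fmt = "png") {
  generate_image_set(dir, n_classes = n_classes, n_per_class = n_per_class,
                     size = size, seed = seed, fmt = fmt)
  dir
}
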
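test_that("single-layer forward rules match hand-computable cases", {
  # identity kernel: centre tap 1, rest 0, stride 1, pad 1, zero bias
  w <- array(0, c(1, 1, 3, 3)); w[1, 1, 2, 2] <- 1
  node <- module_node("c", "conv2d",
                      params = list(in_channels = 1L, out_channels = 1L,
                                    kernel = 3L, stride = 1L, padding = 1L),
                      weights = list(weight = w, bias = 0))
  x <- array(rnorm(9), c(1, 1, 3, 3))
  expect_equal(layer_forward(node, x), x)

  relu <- module_node("r", "relu")
  expect_equal(as.numeric(layer_forward(relu, array(c(-2, 0, 3), c(1, 1, 1, 3)))),
               c(0, 0, 3))

  pool <- module_node("p", "maxpool2d", params = list(kernel = 2L, stride = 2L))
  x22 <- array(c(1, 3, 2, 4), c(1, 1, 2, 2))   # [[1,2],[3,4]] row-major
  expect_equal(as.numeric(layer_forward(pool, x22)), 4)

  drop <- module_node("d", "dropout")
  expect_identical(layer_forward(drop, x), x)
})

test_that("conv2d agrees with the naive quadruple-loop oracle on 50 seeded cases", {
  worst <- 0
  for (seed in 1:50) {
    case <- random_conv_case(seed)
    got <- layer_forward(case$node, case$x)
    want <- naive_conv2d(case$x, case$node$weights$weight, case$node$weights$bias,
                         case$stride, case$padding)
    expect_identical(dim(got), dim(want))
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-6)
})

test_that("spatial output dims obey floor((H + 2p - k)/s) + 1 in every registered architecture", {
  for (arch in list_architectures()) {
    model <- build_architecture(arch, pretrained = FALSE, seed = 0)
    size <- if (arch == "alexnet") 224L else 8L
    x <- array(0, c(1, 3, size, size))
    H <- size
    for (line in enumerate_modules(model)) {
      path <- sub(":.*$", "", line)
      node <- resolve_module(model, path)
      if (node$kind %in% c("conv2d", "maxpool2d")) {
        k <- node$params$kernel
        s <- if (is.null(node$params$stride)) k else node$params$stride
        p <- if (is.null(node$params$padding)) 0L else node$params$padding
        expected <- (H + 2 * p - k) %/% s + 1
        z <- forward_to(model, x, path)
        expect_equal(dim(z)[3], expected, info = paste(arch, path))
        expect_equal(dim(z)[4], expected, info = paste(arch, path))
        H <- expected
      }
    }
  }
})

test_that("forward_to reaches named modules with the documented shapes", {
  toy <- build_architecture("toynet", pretrained = FALSE, seed = 3)
  x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  expect_identical(dim(forward_to(toy, x, "features.2")), c(2L, 4L, 4L, 4L))

  # capturing the final classifier module equals the full forward pass
  out_full <- layer_forward(toy, x, "toynet")
  expect_equal(forward_to(toy, x, "classifier.3"), out_full)

  expect_error(forward_to(toy, x, "bogus.99"), class = "netrsa_address_error")
})

test_that("alexnet follows the canonical recipe", {
  model <- build_architecture("alexnet", pretrained = FALSE, seed = 0)
  node <- resolve_module(model, "features.10")
  expect_equal(node$kind, "conv2d")
  conv_channels <- vapply(
    Filter(function(ch) ch$kind == "conv2d",
           resolve_module(model, "features")$children),
    function(ch) ch$params$out_channels, 0L)
  expect_equal(conv_channels, c(64L, 192L, 384L, 256L, 256L))
  # fifth convolution holds 256 feature maps
  expect_equal(node$params$out_channels, 256L)
})

test_that("weight initialization is a pure function of (seed, path)", {
  a <- build_architecture("toynet", pretrained = FALSE, seed = 7)
  b <- build_architecture("toynet", pretrained = FALSE, seed = 7)
  c <- build_architecture("toynet", pretrained = FALSE, seed = 8)
  wa <- resolve_module(a, "features.0")$weights
  wb <- resolve_module(b, "features.0")$weights
  wc <- resolve_module(c, "features.0")$weights
  expect_identical(wa, wb)
  expect_false(identical(wa, wc))
  # bounds: uniform on (-1/sqrt(fan_in), 1/sqrt(fan_in)), fan_in = 3*3*3
  expect_lt(max(abs(wa$weight)), 1 / sqrt(27))
})

test_that("enumerate_modules lists executable paths with the right leaf prefixes", {
  model <- build_architecture("alexnet", pretrained = FALSE, seed = 0)
  lines <- enumerate_modules(model)
  prefixes <- unique(sub("[.:].*$", "", lines))
  expect_setequal(prefixes, c("features", "avgpool", "classifier"))
  # every printed path round-trips through resolve_module
  for (line in lines) {
    path <- sub(":.*$", "", line)
    expect_silent(resolve_module(model, path))
  }
})

test_that("a three-module architecture file yields exactly three listing lines", {
  spec <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("features.0 conv2d in_channels=3 out_channels=2 kernel=3 stride=1 padding=1",
               "features.1 relu",
               "features.2 maxpool2d kernel=2 stride=2"), spec)
  model <- build_architecture(spec, pretrained = FALSE, seed = 1)
  expect_length(enumerate_modules(model), 3L)
  z <- forward_to(model, array(rnorm(1 * 3 * 6 * 6), c(1, 3, 6, 6)), "features.2")
  expect_identical(dim(z), c(1L, 2L, 3L, 3L))
})

test_that("forward_to is batch-invariant and relu/dropout behave algebraically", {
  toy <- build_architecture("toynet", pretrained = FALSE, seed = 11)
  x <- array(rnorm(4 * 3 * 8 * 8), c(4, 3, 8, 8))
  together <- forward_to(toy, x, "features.2")
  singly <- lapply(1:4, function(i) {
    forward_to(toy, array(x[i, , , ], c(1, 3, 8, 8)), "features.2")
  })
  for (i in 1:4) {
    expect_equal(as.numeric(together[i, , , ]), as.numeric(singly[[i]]),
                 tolerance = 1e-6)
  }
  relu <- module_node("r", "relu")
  v <- array(rnorm(10), c(1, 10))
  expect_identical(layer_forward(relu, layer_forward(relu, v)), layer_forward(relu, v))
})

test_that("batchnorm2d applies stored statistics and shape errors name the module", {
  bn <- module_node("b", "batchnorm2d", params = list(num_features = 2L, eps = 0),
                    weights = list(gamma = c(2, 1), beta = c(1, 0),
                                   mean = c(0.5, 0), var = c(4, 1)))
  x <- array(1, c(1, 2, 2, 2))
  got <- layer_forward(bn, x)
  expect_equal(unique(as.numeric(got[1, 1, , ])), 2 * (1 - 0.5) / 2 + 1)
  expect_equal(unique(as.numeric(got[1, 2, , ])), 1)

  conv <- random_conv_case(1)$node
  bad <- array(0, c(1, conv$params$in_channels + 1, 8, 8))
  err <- expect_error(layer_forward(conv, bad, path = "features.0"),
                      class = "netrsa_shape_error")
  expect_match(conditionMessage(err), "features.0")
})

test_that("weights archives round-trip through HDF5", {
  toy <- build_architecture("toynet", pretrained = FALSE, seed = 5)
  archive <- withr::local_tempfile(fileext = ".h5")
  save_weights_archive(toy, archive)
  loaded <- build_architecture("toynet", pretrained = TRUE, seed = 99, weights = archive)
  expect_equal(resolve_module(loaded, "features.0")$weights,
               resolve_module(toy, "features.0")$weights)
  x <- array(rnorm(1 * 3 * 8 * 8), c(1, 3, 8, 8))
  expect_equal(forward_to(loaded, x, "classifier.3"), forward_to(toy, x, "classifier.3"))
  expect_error(build_architecture("toynet", pretrained = TRUE, seed = 0),
               class = "netrsa_weights_error")
  expect_error(build_architecture("nonexistent_net", FALSE, 0),
               class = "netrsa_registry_error")
})
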
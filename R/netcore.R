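# Deterministic inference engine: module trees, per-kind forward rules, an
# architecture registry (alexnet, toynet) and seeded weight initialization.
# Convolution is evaluated as im2col + one BLAS matrix multiply per layer, so
# a full AlexNet pass at 224 px takes on the order of a second on one CPU.

.NODE_KINDS <- c("sequential", "conv2d", "relu", "maxpool2d",
                 "adaptive_avgpool2d", "linear", "dropout", "batchnorm2d",
                 "flatten")

#' Create a module node
#'
#' A module node is one named element of a model's computation tree: a
#' convolution, non-linearity, pooling operation, affine map, or a
#' `sequential` container holding an ordered list of children.
#'
#' @param name node name (e.g. `"features"` or `"3"`).
#' @param kind one of `sequential`, `conv2d`, `relu`, `maxpool2d`,
#'   `adaptive_avgpool2d`, `linear`, `dropout`, `batchnorm2d`, `flatten`.
#' @param params named list of kind-specific parameters (e.g. `kernel`,
#'   `stride`, `padding`, `in_channels`, `out_channels`, `in_features`,
#'   `out_features`, `target`, `eps`).
#' @param weights named list of numeric blocks (`weight`, `bias`, and for
#'   batchnorm `gamma`, `beta`, `mean`, `var`).
#' @param children ordered list of child nodes; non-empty iff `kind` is
#'   `"sequential"`.
#' @return an object of class `module_node`.
#' @export
module_node <- function(name, kind, params = list(), weights = list(),
                        children = list()) {
  if (!kind %in% .NODE_KINDS) {
    nr_error("netrsa_kind_error",
             sprintf("unknown module kind '%s' (valid: %s)", kind,
                     paste(.NODE_KINDS, collapse = ", ")))
  }
  if ((kind == "sequential") != (length(children) > 0L)) {
    nr_error("netrsa_tree_error",
             "children must be non-empty exactly when kind is 'sequential'")
  }
  structure(list(name = as.character(name), kind = kind, params = params,
                 weights = weights, children = children),
            class = "module_node")
}

# ---------------------------------------------------------------------------
# Per-kind forward rules. x is B x C x H x W (channels first) for spatial
# kinds, B x F for linear; the batch axis always comes first.

.conv_out_dim <- function(size, kernel, stride, padding) {
  (size + 2L * padding - kernel) %/% stride + 1L
}

.check_4d <- function(x, path) {
  if (length(dim(x)) != 4L) {
    nr_error("netrsa_shape_error",
             sprintf("module '%s' expects a 4-D B x C x H x W block, got %s",
                     path, paste(dim(x) %||% length(x), collapse = "x")))
  }
}

.pad_spatial <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1], d[2], d[3] + 2L * p, d[4] + 2L * p))
  out[, , p + seq_len(d[3]), p + seq_len(d[4])] <- x
  out
}

.forward_conv2d <- function(node, x, path) {
  .check_4d(x, path)
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  p <- node$params
  k <- p$kernel; s <- p$stride %||% 1L; pad <- p$padding %||% 0L
  if (C != p$in_channels) {
    nr_error("netrsa_shape_error",
             sprintf("module '%s' expects %d input channels, got %d",
                     path, p$in_channels, C))
  }
  Ho <- .conv_out_dim(H, k, s, pad); Wo <- .conv_out_dim(W, k, s, pad)
  if (Ho < 1L || Wo < 1L) {
    nr_error("netrsa_shape_error",
             sprintf("module '%s': input %dx%d too small for kernel %d stride %d pad %d",
                     path, H, W, k, s, pad))
  }
  xp <- .pad_spatial(x, pad)
  i0 <- seq.int(1L, by = s, length.out = Ho)
  j0 <- seq.int(1L, by = s, length.out = Wo)
  # im2col: patches indexed (C, kH, kW) x (B, Ho, Wo)
  patches <- array(0, dim = c(B, C, k, k, Ho, Wo))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      patches[, , di, dj, , ] <- xp[, , i0 + di - 1L, j0 + dj - 1L, drop = FALSE]
    }
  }
  pm <- aperm(patches, c(2, 3, 4, 1, 5, 6))
  dim(pm) <- c(C * k * k, B * Ho * Wo)
  wm <- aperm(node$weights$weight, c(2, 3, 4, 1))   # (C,kH,kW,K) -> cols per filter
  K <- p$out_channels
  dim(wm) <- c(C * k * k, K)
  out <- crossprod(wm, pm) + node$weights$bias      # K x (B*Ho*Wo)
  dim(out) <- c(K, B, Ho, Wo)
  aperm(out, c(2, 1, 3, 4))
}

.forward_maxpool2d <- function(node, x, path) {
  .check_4d(x, path)
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  k <- node$params$kernel; s <- node$params$stride %||% k
  Ho <- .conv_out_dim(H, k, s, 0L); Wo <- .conv_out_dim(W, k, s, 0L)
  if (Ho < 1L || Wo < 1L) {
    nr_error("netrsa_shape_error",
             sprintf("module '%s': input %dx%d too small for pool kernel %d", path, H, W, k))
  }
  i0 <- seq.int(1L, by = s, length.out = Ho)
  j0 <- seq.int(1L, by = s, length.out = Wo)
  out <- array(-Inf, dim = c(B, C, Ho, Wo))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      out <- pmax(out, x[, , i0 + di - 1L, j0 + dj - 1L, drop = FALSE])
    }
  }
  out
}

.forward_adaptive_avgpool2d <- function(node, x, path) {
  .check_4d(x, path)
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  tg <- node$params$target
  th <- tg[1]; tw <- if (length(tg) > 1L) tg[2] else tg[1]
  out <- array(0, dim = c(B, C, th, tw))
  for (i in seq_len(th)) {
    hi <- (floor((i - 1) * H / th) + 1L):ceiling(i * H / th)
    for (j in seq_len(tw)) {
      wj <- (floor((j - 1) * W / tw) + 1L):ceiling(j * W / tw)
      block <- x[, , hi, wj, drop = FALSE]
      out[, , i, j] <- apply(block, c(1, 2), mean)
    }
  }
  out
}

# Flatten a 4-D block to B x (K*H*W) in channel-major order: for each image
# the vector iterates width fastest, then height, then channel.
.flatten_block <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) return(x)
  m <- aperm(x, c(4, 3, 2, 1))
  dim(m) <- c(prod(d[-1]), d[1])
  t(m)
}

.unflatten_block <- function(m, dims_khw) {
  stopifnot(length(dims_khw) == 3L)
  x <- t(m)
  dim(x) <- c(rev(dims_khw), nrow(m))
  aperm(x, c(4, 3, 2, 1))
}

.forward_linear <- function(node, x, path) {
  if (length(dim(x)) == 4L) x <- .flatten_block(x)
  if (is.null(dim(x)) || length(dim(x)) != 2L) {
    nr_error("netrsa_shape_error", sprintf("module '%s' expects a 2-D block", path))
  }
  p <- node$params
  if (ncol(x) != p$in_features) {
    nr_error("netrsa_shape_error",
             sprintf("module '%s' expects %d input features, got %d",
                     path, p$in_features, ncol(x)))
  }
  sweep(x %*% t(node$weights$weight), 2, node$weights$bias, "+")
}

.forward_batchnorm2d <- function(node, x, path) {
  .check_4d(x, path)
  w <- node$weights
  eps <- node$params$eps %||% 1e-5
  d <- dim(x)
  scale <- w$gamma / sqrt(w$var + eps)
  shift <- w$beta - w$mean * scale
  # broadcast over the channel axis (axis 2)
  x * array(rep(scale, each = d[1]), dim = d) +
    array(rep(shift, each = d[1]), dim = d)
}

#' Apply a single module's forward rule
#'
#' Evaluates one node on a batch: zero-padded cross-correlation for `conv2d`
#' (output spatial size `floor((H + 2p - k)/s) + 1`), elementwise
#' `max(0, x)` for `relu`, windowed maximum for `maxpool2d`, binned means for
#' `adaptive_avgpool2d`, an affine map for `linear`, identity for `dropout`
#' (inference mode), stored-statistics normalization for `batchnorm2d`, and
#' channel-major reshaping for `flatten`.
#'
#' @param node a [module_node()] (non-sequential).
#' @param x numeric block, `B x C x H x W` for spatial kinds or `B x F` for
#'   `linear`.
#' @param path node path used in error messages.
#' @return the module output block.
#' @export
layer_forward <- function(node, x, path = node$name) {
  switch(node$kind,
    conv2d = .forward_conv2d(node, x, path),
    relu = pmax(x, 0),
    maxpool2d = .forward_maxpool2d(node, x, path),
    adaptive_avgpool2d = .forward_adaptive_avgpool2d(node, x, path),
    linear = .forward_linear(node, x, path),
    dropout = x,
    batchnorm2d = .forward_batchnorm2d(node, x, path),
    flatten = .flatten_block(x),
    sequential = {
      for (child in node$children) {
        x <- layer_forward(child, x, paste(path, child$name, sep = "."))
      }
      x
    }
  )
}

# ---------------------------------------------------------------------------
# Path addressing

# All execution-order (path, node) pairs below `node`, including sequential
# containers themselves (a container's output is its last child's output).
.walk_paths <- function(node, prefix = NULL) {
  path <- if (is.null(prefix)) node$name else paste(prefix, node$name, sep = ".")
  out <- list()
  if (node$kind == "sequential") {
    for (child in node$children) out <- c(out, .walk_paths(child, path))
  }
  c(out, list(list(path = path, node = node)))
}

# Paths relative to the root: the root's own name is dropped, matching the
# convention that addressing starts at the leaves directly below the root.
.model_paths <- function(model) {
  out <- list()
  for (child in model$children) out <- c(out, .walk_paths(child, NULL))
  out
}

#' Resolve a period-separated module path
#'
#' Module addresses are composed of a leaf directly below the model root and
#' zero or more child indices, separated by periods (e.g. `"features.10"`).
#'
#' @param model root [module_node()].
#' @param module_name period-separated path string.
#' @return the addressed `module_node`.
#' @export
resolve_module <- function(model, module_name) {
  if (!is_scalar_character(module_name) || !nzchar(module_name)) {
    nr_error("netrsa_address_error", "module_name must be a non-empty string")
  }
  parts <- strsplit(module_name, ".", fixed = TRUE)[[1]]
  node <- model
  for (part in parts) {
    idx <- match(part, vapply(node$children, `[[`, "", "name"))
    if (is.na(idx)) {
      leaves <- vapply(model$children, `[[`, "", "name")
      nr_error("netrsa_address_error",
               sprintf("module path not found: '%s' (valid leaf names: %s)",
                       module_name, paste(leaves, collapse = ", ")))
    }
    node <- node$children[[idx]]
  }
  node
}

#' Run a batch forward to a named module and capture its output
#'
#' Executes the model's modules in registered order and returns the output of
#' the addressed module; for convolutional targets the result is
#' `B x K x H' x W'` where `K` is the number of feature maps.
#'
#' @param model root [module_node()].
#' @param batch `B x C x H x W` numeric block.
#' @param target_path period-separated module address.
#' @return the activation block at `target_path`.
#' @export
forward_to <- function(model, batch, target_path) {
  resolve_module(model, target_path)   # fail fast on a bad address
  captured <- NULL
  run <- function(node, x, prefix) {
    path <- if (is.null(prefix)) node$name else paste(prefix, node$name, sep = ".")
    if (node$kind == "sequential") {
      for (child in node$children) {
        x <- run(child, x, path)
        if (!is.null(captured)) return(x)
      }
    } else {
      x <- layer_forward(node, x, path)
    }
    if (identical(path, target_path)) captured <<- x
    x
  }
  x <- batch
  for (child in model$children) {
    x <- run(child, x, NULL)
    if (!is.null(captured)) break
  }
  if (is.null(captured)) {
    nr_error("netrsa_address_error",
             sprintf("module path not found during execution: '%s'", target_path))
  }
  captured
}

# ---------------------------------------------------------------------------
# Weight initialization and the architecture registry

# Uniform on (-1/sqrt(fan_in), +1/sqrt(fan_in)), drawn from a stream keyed by
# (seed, module path) so weights are reproducible per module.
.init_node_weights <- function(node, seed, path) {
  if (node$kind == "conv2d") {
    p <- node$params
    fan_in <- p$in_channels * p$kernel^2
    bound <- 1 / sqrt(fan_in)
    node$weights <- with_local_seed(seed, path, list(
      weight = array(runif(p$out_channels * p$in_channels * p$kernel^2, -bound, bound),
                     dim = c(p$out_channels, p$in_channels, p$kernel, p$kernel)),
      bias = runif(p$out_channels, -bound, bound)
    ))
  } else if (node$kind == "linear") {
    p <- node$params
    bound <- 1 / sqrt(p$in_features)
    node$weights <- with_local_seed(seed, path, list(
      weight = matrix(runif(p$out_features * p$in_features, -bound, bound),
                      nrow = p$out_features),
      bias = runif(p$out_features, -bound, bound)
    ))
  } else if (node$kind == "batchnorm2d") {
    nf <- node$params$num_features
    node$weights <- list(gamma = rep(1, nf), beta = rep(0, nf),
                         mean = rep(0, nf), var = rep(1, nf))
  } else if (node$kind == "sequential") {
    node$children <- lapply(node$children, function(ch) {
      .init_node_weights(ch, seed, paste(path, ch$name, sep = "."))
    })
  }
  node
}

.seq_leaf <- function(name, specs) {
  children <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    module_node(name = as.character(i - 1L), kind = sp$kind,
                params = sp[setdiff(names(sp), "kind")])
  })
  module_node(name, "sequential", children = children)
}

.recipe_alexnet <- function() {
  features <- .seq_leaf("features", list(
    list(kind = "conv2d", in_channels = 3L, out_channels = 64L, kernel = 11L, stride = 4L, padding = 2L),
    list(kind = "relu"),
    list(kind = "maxpool2d", kernel = 3L, stride = 2L),
    list(kind = "conv2d", in_channels = 64L, out_channels = 192L, kernel = 5L, stride = 1L, padding = 2L),
    list(kind = "relu"),
    list(kind = "maxpool2d", kernel = 3L, stride = 2L),
    list(kind = "conv2d", in_channels = 192L, out_channels = 384L, kernel = 3L, stride = 1L, padding = 1L),
    list(kind = "relu"),
    list(kind = "conv2d", in_channels = 384L, out_channels = 256L, kernel = 3L, stride = 1L, padding = 1L),
    list(kind = "relu"),
    list(kind = "conv2d", in_channels = 256L, out_channels = 256L, kernel = 3L, stride = 1L, padding = 1L),
    list(kind = "relu"),
    list(kind = "maxpool2d", kernel = 3L, stride = 2L)
  ))
  avgpool <- module_node("avgpool", "adaptive_avgpool2d", params = list(target = c(6L, 6L)))
  classifier <- .seq_leaf("classifier", list(
    list(kind = "dropout"),
    list(kind = "linear", in_features = 256L * 6L * 6L, out_features = 4096L),
    list(kind = "relu"),
    list(kind = "dropout"),
    list(kind = "linear", in_features = 4096L, out_features = 4096L),
    list(kind = "relu"),
    list(kind = "linear", in_features = 4096L, out_features = 1000L)
  ))
  module_node("alexnet", "sequential", children = list(features, avgpool, classifier))
}

.recipe_toynet <- function(input_size = 8L) {
  half <- input_size %/% 2L
  features <- .seq_leaf("features", list(
    list(kind = "conv2d", in_channels = 3L, out_channels = 4L, kernel = 3L, stride = 1L, padding = 1L),
    list(kind = "relu"),
    list(kind = "maxpool2d", kernel = 2L, stride = 2L)
  ))
  classifier <- .seq_leaf("classifier", list(
    list(kind = "flatten"),
    list(kind = "linear", in_features = 4L * half * half, out_features = 8L),
    list(kind = "relu"),
    list(kind = "linear", in_features = 8L, out_features = 3L)
  ))
  module_node("toynet", "sequential", children = list(features, classifier))
}

# Registry: recipe constructor plus the input-side transform each
# architecture expects (resize shorter side / centre crop / normalization).
.ARCH_REGISTRY <- list(
  alexnet = list(recipe = function() .recipe_alexnet(),
                 transform = function() transform_spec()),
  toynet = list(recipe = function() .recipe_toynet(),
                transform = function() transform_spec(resize = 8L, crop = 8L,
                                                      mean = rep(0.5, 3), std = rep(0.5, 3)))
)

#' Names of registered architectures
#' @return character vector.
#' @export
list_architectures <- function() names(.ARCH_REGISTRY)

#' Default input transform for a registered architecture
#'
#' @param name architecture name.
#' @return a [transform_spec()].
#' @export
default_transform <- function(name) {
  if (!name %in% names(.ARCH_REGISTRY)) {
    nr_error("netrsa_registry_error",
             sprintf("unknown architecture '%s' (registered: %s)", name,
                     paste(names(.ARCH_REGISTRY), collapse = ", ")))
  }
  .ARCH_REGISTRY[[name]]$transform()
}

#' Build a model tree from the registry or an architecture file
#'
#' Registered recipes: `alexnet` (the canonical 5-convolution / 3-linear
#' layout whose leaves are `features`, `avgpool` and `classifier`, so that
#' `features.10` is the fifth convolution with 256 feature maps) and `toynet`
#' (a minimal convolution/pool/linear tree for fast tests). With
#' `pretrained = FALSE`, every convolution and linear module gets weights
#' drawn uniformly on `(-1/sqrt(fan_in), +1/sqrt(fan_in))` from a stream keyed
#' by `(seed, module path)`; with `pretrained = TRUE`, weights are loaded from
#' a local HDF5 archive (see [load_weights_archive()]).
#'
#' @param name registry name or path to an architecture description file
#'   (see [read_architecture_file()]).
#' @param pretrained logical; load weights from `weights` instead of random
#'   initialization.
#' @param seed non-negative integer governing random initialization.
#' @param weights path to an HDF5 weights archive, required when
#'   `pretrained = TRUE`.
#' @return root [module_node()].
#' @export
build_architecture <- function(name, pretrained = FALSE, seed = 0L, weights = NULL) {
  if (name %in% names(.ARCH_REGISTRY)) {
    model <- .ARCH_REGISTRY[[name]]$recipe()
  } else if (file.exists(name)) {
    model <- read_architecture_file(name)
  } else {
    nr_error("netrsa_registry_error",
             sprintf("unknown architecture '%s' (registered: %s)", name,
                     paste(names(.ARCH_REGISTRY), collapse = ", ")))
  }
  model <- .init_node_weights(model, seed, model$name)
  if (isTRUE(pretrained)) {
    if (is.null(weights)) {
      nr_error("netrsa_weights_error",
               "pretrained = TRUE requires a local weights archive (weights = <path>)")
    }
    model <- load_weights_archive(model, weights)
  }
  model
}

#' Read an architecture description file
#'
#' Flat text, one module per line: `<leaf>[.<index>] <kind> key=val ...`,
#' e.g. `features.0 conv2d in_channels=3 out_channels=4 kernel=3 padding=1`.
#' Consecutive lines sharing a leaf prefix are grouped into a sequential
#' container; a line with a bare leaf name defines a single-module leaf.
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @param name model name for the root node.
#' @return root [module_node()] (weights uninitialized).
#' @export
read_architecture_file <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) nr_error("netrsa_registry_error", sprintf("empty architecture file '%s'", path))
  entries <- lapply(lines, function(ln) {
    toks <- strsplit(ln, "\\s+")[[1]]
    addr <- strsplit(toks[1], ".", fixed = TRUE)[[1]]
    params <- list()
    for (tok in toks[-(1:2)]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      val <- suppressWarnings(as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]]))
      params[[kv[1]]] <- if (anyNA(val)) kv[2] else val
    }
    list(leaf = addr[1], child = if (length(addr) > 1L) addr[2] else NA_character_,
         kind = toks[2], params = params)
  })
  leaves <- unique(vapply(entries, `[[`, "", "leaf"))
  children <- lapply(leaves, function(lf) {
    ents <- Filter(function(e) e$leaf == lf, entries)
    if (length(ents) == 1L && is.na(ents[[1]]$child)) {
      module_node(lf, ents[[1]]$kind, params = ents[[1]]$params)
    } else {
      module_node(lf, "sequential", children = lapply(ents, function(e) {
        module_node(e$child, e$kind, params = e$params)
      }))
    }
  })
  module_node(name, "sequential", children = children)
}

#' Load module weights from an HDF5 archive
#'
#' The archive holds one HDF5 group per module path (periods replaced by
#' `/`), with datasets named `weight`, `bias`, `gamma`, `beta`, `mean`,
#' `var` as applicable.
#'
#' @param model root [module_node()] with initialized structure.
#' @param path HDF5 file path.
#' @return the model with weights replaced where the archive provides them.
#' @export
load_weights_archive <- function(model, path) {
  if (!file.exists(path)) {
    nr_error("netrsa_weights_error", sprintf("weights archive not found: '%s'", path))
  }
  contents <- rhdf5::h5ls(path)
  groups <- unique(dirname(paste0(contents$group, "/", contents$name)))
  apply_weights <- function(node, prefix) {
    p <- if (is.null(prefix)) node$name else paste(prefix, node$name, sep = ".")
    if (node$kind == "sequential") {
      node$children <- lapply(node$children, apply_weights, prefix = p)
    } else if (length(node$weights)) {
      grp <- paste0("/", gsub(".", "/", p, fixed = TRUE))
      if (grp %in% groups) {
        for (nm in names(node$weights)) {
          ds <- paste0(grp, "/", nm)
          val <- tryCatch(rhdf5::h5read(path, ds), error = function(e) NULL)
          if (!is.null(val)) {
            if (is.null(dim(node$weights[[nm]]))) {
              val <- as.vector(val)
            } else {
              dim(val) <- dim(node$weights[[nm]])
            }
            node$weights[[nm]] <- val
          }
        }
      }
    }
    node
  }
  model$children <- lapply(model$children, apply_weights, prefix = NULL)
  model
}

#' Save a model's weights to an HDF5 archive
#'
#' @param model root [module_node()].
#' @param path output HDF5 file path (overwritten).
#' @return `path`, invisibly.
#' @export
save_weights_archive <- function(model, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (entry in .model_paths(model)) {
    node <- entry$node
    if (node$kind == "sequential" || !length(node$weights)) next
    parts <- strsplit(entry$path, ".", fixed = TRUE)[[1]]
    for (depth in seq_along(parts)) {
      sub <- paste(parts[seq_len(depth)], collapse = "/")
      suppressWarnings(rhdf5::h5createGroup(path, sub))  # FALSE if it exists
    }
    grp <- paste(parts, collapse = "/")
    for (nm in names(node$weights)) {
      rhdf5::h5write(node$weights[[nm]], path, paste0(grp, "/", nm))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

.param_string <- function(node) {
  p <- node$params
  fmt <- function(x) paste(x, collapse = "x")
  switch(node$kind,
    conv2d = sprintf("in=%d, out=%d, kernel=%d, stride=%d, padding=%d",
                     p$in_channels, p$out_channels, p$kernel,
                     p$stride %||% 1L, p$padding %||% 0L),
    maxpool2d = sprintf("kernel=%d, stride=%d", p$kernel, p$stride %||% p$kernel),
    adaptive_avgpool2d = sprintf("target=%s", fmt(p$target)),
    linear = sprintf("in=%d, out=%d", p$in_features, p$out_features),
    batchnorm2d = sprintf("features=%d, eps=%g", p$num_features, p$eps %||% 1e-5),
    ""
  )
}

#' List a model's modules in execution order
#'
#' One line per non-sequential node, `"<path>: <kind>(<params>)"`, in the
#' order the modules execute. Use this to choose a `module_name` address for
#' extraction.
#'
#' @param model root [module_node()].
#' @return character vector of lines, invisibly when printed via `cat`.
#' @export
enumerate_modules <- function(model) {
  entries <- Filter(function(e) e$node$kind != "sequential", .model_paths(model))
  vapply(entries, function(e) {
    sprintf("%s: %s(%s)", e$path, e$node$kind, .param_string(e$node))
  }, "")
}

#' @export
print.module_node <- function(x, ...) {
  cat(sprintf("<module_node> %s (%s)\n", x$name, x$kind))
  if (x$kind == "sequential") cat(paste0("  ", enumerate_modules(x), "\n"), sep = "")
  invisible(x)
}
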
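# Batched activation capture at a named module, flattening K x H x W blocks
# into one vector per image, and assembly of the N x D feature matrix with
# row-order provenance.

#' Construct a feature matrix object
#'
#' @param values `N x D` numeric matrix.
#' @param row_names relative image paths, one per row.
#' @param targets integer class indices, one per row.
#' @param module period-separated source module path.
#' @param flattened logical; whether rows are flattened activations.
#' @param dims original `(K, H, W)` activation dimensions when flattened from
#'   a 4-D block, else `NULL`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, row_names = NULL, targets = NULL,
                           module = NA_character_, flattened = TRUE, dims = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  structure(list(values = values,
                 row_names = row_names %||% as.character(seq_len(n) - 1L),
                 targets = as.integer(targets %||% rep(0L, n)),
                 module = module, flattened = flattened, dims = dims),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d from module '%s'%s\n",
              nrow(x$values), ncol(x$values), x$module,
              if (!is.null(x$dims)) sprintf(" (flattened from %s)", paste(x$dims, collapse = "x")) else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Construct an activation tensor object
#'
#' @param values `N x K x H x W` numeric block.
#' @param row_names,targets,module as in [feature_matrix()].
#' @return object of class `activation_tensor`.
#' @export
activation_tensor <- function(values, row_names = NULL, targets = NULL,
                              module = NA_character_) {
  n <- dim(values)[1]
  structure(list(values = values,
                 row_names = row_names %||% as.character(seq_len(n) - 1L),
                 targets = as.integer(targets %||% rep(0L, n)),
                 module = module),
            class = "activation_tensor")
}

#' @export
print.activation_tensor <- function(x, ...) {
  cat(sprintf("<activation_tensor> %s from module '%s'\n",
              paste(dim(x$values), collapse = " x "), x$module))
  invisible(x)
}

#' @export
dim.activation_tensor <- function(x) dim(x$values)

#' Flatten activations to one vector per image
#'
#' Reshapes a `B x K x H x W` block to `B x (K*H*W)` in channel-major order:
#' within each row, the width index varies fastest, then height, then
#' channel. 2-D input is returned unchanged.
#'
#' @param x 4-D or 2-D numeric block.
#' @return `B x D` matrix.
#' @export
flatten_activations <- function(x) .flatten_block(x)

#' Invert [flatten_activations()] given the stored dimensions
#'
#' @param m `B x (K*H*W)` matrix.
#' @param dims integer vector `(K, H, W)`.
#' @return `B x K x H x W` array.
#' @export
unflatten_activations <- function(m, dims) {
  if (prod(dims) != ncol(m)) {
    nr_error("netrsa_shape_error",
             sprintf("dims %s do not match %d columns", paste(dims, collapse = "x"), ncol(m)))
  }
  .unflatten_block(as.matrix(m), dims)
}

#' Extract activations for a dataset at a named module
#'
#' Runs every batch forward to `module_name`, captures the module output
#' `Z` (`B x K x H' x W'` for convolutional targets), optionally flattens each
#' image's activation to a `K*H*W` vector, and concatenates over batches into
#' an `N x D` feature matrix whose row `i` corresponds to line `i` of the
#' order record. The integer target vector (class indices) is always
#' attached; callers may save or ignore it.
#'
#' @param model root [module_node()].
#' @param batches list of batches from [batch_iterator()], or a single batch.
#' @param module_name period-separated module address.
#' @param flatten_acts logical; flatten to `N x (K*H*W)` (`TRUE`) or keep the
#'   original 4-D block (`FALSE`). No default: the choice depends on the
#'   downstream analysis.
#' @param row_names optional relative paths naming the rows (taken from
#'   `dataset$records$path` by the CLI).
#' @return a [feature_matrix()] when `flatten_acts = TRUE` or the target
#'   module output is 2-D; otherwise an [activation_tensor()].
#' @export
extract_features <- function(model, batches, module_name, flatten_acts,
                             row_names = NULL) {
  if (inherits(batches, "batch")) batches <- list(batches)
  if (!length(batches)) nr_error("netrsa_input_error", "no batches to extract from")
  resolve_module(model, module_name)
  outs <- vector("list", length(batches))
  targets <- integer(0)
  positions <- integer(0)
  ref_dims <- NULL
  for (b in seq_along(batches)) {
    batch <- batches[[b]]
    is_rec <- inherits(batch, "batch") || (is.list(batch) && !is.null(batch$data))
    x <- if (is_rec) batch$data else batch
    if (is_rec && length(dim(x)) == 4L && identical(batch$layout, "channels_last")) {
      x <- aperm(x, c(1, 4, 2, 3))   # engine is channels-first internally
    }
    z <- forward_to(model, x, module_name)
    item_dims <- dim(z)[-1]
    if (is.null(ref_dims)) {
      ref_dims <- item_dims
    } else if (!identical(ref_dims, item_dims)) {
      nr_error("netrsa_internal_error",
               sprintf("inconsistent activation dims across batches: %s vs %s",
                       paste(ref_dims, collapse = "x"), paste(item_dims, collapse = "x")))
    }
    outs[[b]] <- z
    targets <- c(targets,
                 if (is_rec) batch$labels %||% rep(0L, dim(z)[1]) else rep(0L, dim(z)[1]))
    positions <- c(positions, if (is_rec) batch$positions %||% integer(0) else integer(0))
  }
  n <- sum(vapply(outs, function(z) dim(z)[1], 0))
  names_out <- row_names %||% as.character(seq_len(n) - 1L)
  was_4d <- length(ref_dims) == 3L
  if (isTRUE(flatten_acts) || !was_4d) {
    mats <- lapply(outs, .flatten_block)
    values <- do.call(rbind, mats)
    feature_matrix(values, row_names = names_out, targets = targets,
                   module = module_name, flattened = was_4d,
                   dims = if (was_4d) ref_dims else NULL)
  } else {
    values <- array(0, dim = c(n, ref_dims))
    at <- 0L
    for (z in outs) {
      bsz <- dim(z)[1]
      values[at + seq_len(bsz), , , ] <- z
      at <- at + bsz
    }
    activation_tensor(values, row_names = names_out, targets = targets,
                      module = module_name)
  }
}
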
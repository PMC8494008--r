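# Persistence of feature matrices and activation tensors in four formats
# (npy, txt, mat, hdf5), k-way row splits for memory-constrained saves, and
# 4-D <-> 2-D slicing round trips. Fixed conventions: the MAT variable and
# HDF5 dataset are named "features" with targets in "targets"; npy/txt carry
# a JSON sidecar with module path, flatten order and original dims; txt is
# one row per line, space-separated, scientific notation with 8 significant
# digits.

.FILE_FORMATS <- c("npy", "txt", "mat", "hdf5")

.check_format <- function(file_format) {
  if (!is_scalar_character(file_format) || !file_format %in% .FILE_FORMATS) {
    nr_error("netrsa_config_error",
             sprintf("unknown file_format '%s': must be one of npy, txt, mat, hdf5",
                     as.character(file_format)[1]))
  }
  file_format
}

.format_ext <- function(file_format) {
  switch(file_format, npy = "npy", txt = "txt", mat = "mat", hdf5 = "h5")
}

.ensure_dir <- function(path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE)) {
    nr_error("netrsa_io_error", sprintf("cannot create directory '%s'", path))
  }
  path
}

.features_meta <- function(x) {
  if (inherits(x, "feature_matrix")) {
    list(module = x$module, flattened = x$flattened,
         flatten_order = "channel_major", dims = x$dims,
         row_names = x$row_names, targets = x$targets)
  } else if (inherits(x, "activation_tensor")) {
    list(module = x$module, flattened = FALSE,
         flatten_order = "channel_major", dims = dim(x$values)[-1],
         row_names = x$row_names, targets = x$targets)
  } else {
    NULL
  }
}

.values_of <- function(x) {
  if (inherits(x, "feature_matrix") || inherits(x, "activation_tensor")) x$values else x
}

.write_txt_matrix <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- apply(m, 1, function(row) paste(formatC(row, digits = 8, format = "e"), collapse = " "))
  writeLines(lines, con, sep = "\n")
  path
}

.read_txt_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  do.call(rbind, lapply(strsplit(lines, " ", fixed = TRUE), as.numeric))
}

.write_hdf5 <- function(values, path, meta = NULL) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(values, path, "features")
  if (!is.null(meta)) {
    rhdf5::h5write(as.integer(meta$targets), path, "targets")
    rhdf5::h5write(meta$row_names, path, "row_names")
    rhdf5::h5write(
      as.character(jsonlite::toJSON(meta[c("module", "flattened", "flatten_order", "dims")],
                                    auto_unbox = TRUE, null = "null")),
      path, "metadata")
  }
  rhdf5::h5closeAll()
  path
}

#' Save features to disk
#'
#' Two-dimensional feature matrices can be written in any of the four
#' formats. Four-dimensional activation tensors keep their original shape
#' and therefore require `hdf5`, `npy` or `mat`; requesting `txt` for a 4-D
#' block is an error (slice it first with [tensor_to_slices()]). For `npy`
#' and `txt`, provenance (module path, flatten order, original dims, row
#' names, targets) goes to a JSON sidecar `<stem>_meta.json`; targets are
#' additionally written as `targets.<ext>`.
#'
#' @param features a [feature_matrix()], [activation_tensor()], or bare
#'   numeric matrix/array.
#' @param out_path output directory (created if needed).
#' @param file_format one of `"npy"`, `"txt"`, `"mat"`, `"hdf5"`.
#' @param stem file stem, default `"features"`.
#' @return character vector of written file paths, invisibly.
#' @export
save_features <- function(features, out_path, file_format = "npy", stem = "features") {
  .check_format(file_format)
  .ensure_dir(out_path)
  values <- .values_of(features)
  meta <- .features_meta(features)
  nd <- length(dim(values) %||% c(length(values)))
  if (nd > 2L && file_format == "txt") {
    nr_error("netrsa_format_error",
             paste("cannot save a 4-D tensor as txt; set the file format to",
                   "hdf5, npy, or mat, or slice it with tensor_to_slices()"))
  }
  ext <- .format_ext(file_format)
  main <- file.path(out_path, paste0(stem, ".", ext))
  written <- switch(file_format,
    npy = write_npy(values, main),
    txt = .write_txt_matrix(values, main),
    mat = {
      vars <- list(features = values)
      if (!is.null(meta)) vars$targets <- as.numeric(meta$targets)
      write_mat5(vars, main)
    },
    hdf5 = .write_hdf5(values, main, meta)
  )
  written <- main
  out <- written
  if (file_format %in% c("npy", "txt") && !is.null(meta)) {
    tpath <- file.path(out_path, paste0("targets.", ext))
    if (file_format == "npy") write_npy(as.numeric(meta$targets), tpath)
    else writeLines(as.character(meta$targets), tpath)
    meta_path <- file.path(out_path, paste0(stem, "_meta.json"))
    jsonlite::write_json(meta[c("module", "flattened", "flatten_order", "dims", "row_names")],
                         meta_path, auto_unbox = TRUE, null = "null", digits = NA)
    out <- c(out, tpath, meta_path)
  }
  invisible(out)
}

#' Load features saved by [save_features()]
#'
#' @param out_path directory holding the files.
#' @param file_format one of `"npy"`, `"txt"`, `"mat"`, `"hdf5"`.
#' @param stem file stem, default `"features"`.
#' @return numeric matrix or array (bare values; sidecar metadata is read
#'   into attributes `module` and `dims` when available).
#' @export
load_features <- function(out_path, file_format = "npy", stem = "features") {
  .check_format(file_format)
  main <- file.path(out_path, paste0(stem, ".", .format_ext(file_format)))
  if (!file.exists(main)) {
    nr_error("netrsa_io_error", sprintf("no %s features file at '%s'", file_format, main))
  }
  values <- switch(file_format,
    npy = read_npy(main),
    txt = .read_txt_matrix(main),
    mat = read_mat5(main)$features,
    hdf5 = {
      v <- rhdf5::h5read(main, "features")
      rhdf5::h5closeAll()
      v
    }
  )
  meta_path <- file.path(out_path, paste0(stem, "_meta.json"))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(values, "module") <- meta$module
    attr(values, "dims") <- meta$dims
  }
  values
}

.split_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  c(rep(base + 1L, rem), rep(base, k - rem))
}

.split_stem <- function(i, k) sprintf("features_%0*d_of_%d", nchar(as.character(k)), i, k)

#' Split a feature matrix row-wise and save the parts
#'
#' Partitions the rows into `n_splits` contiguous, equally large parts (the
#' first `N mod k` parts get one extra row) and saves each with
#' [save_features()] under zero-padded names `features_<i>_of_<k>.<ext>`.
#' The default of 10 splits counters memory errors when saving flattened
#' convolutional activations; use multiples of 10 if that is not enough.
#'
#' @param features matrix or [feature_matrix()].
#' @param out_path output directory.
#' @param file_format one of `"npy"`, `"txt"`, `"mat"`, `"hdf5"`.
#' @param n_splits number of parts `k`, `1 <= k <= N`.
#' @return character vector of the `n_splits` main file paths, invisibly.
#' @export
split_and_save <- function(features, out_path, file_format = "npy", n_splits = 10L) {
  .check_format(file_format)
  values <- .values_of(features)
  if (length(dim(values)) != 2L) {
    nr_error("netrsa_format_error", "split_and_save() operates on 2-D feature matrices")
  }
  n <- nrow(values)
  if (!is_count(n_splits) || n_splits > n) {
    nr_error("netrsa_range_error",
             sprintf("n_splits must be an integer in [1, %d], got %s", n, as.character(n_splits)))
  }
  .ensure_dir(out_path)
  sizes <- .split_sizes(n, as.integer(n_splits))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  paths <- character(n_splits)
  ext <- .format_ext(file_format)
  for (i in seq_len(n_splits)) {
    part <- values[starts[i]:ends[i], , drop = FALSE]
    stem <- .split_stem(i, n_splits)
    main <- file.path(out_path, paste0(stem, ".", ext))
    switch(file_format,
      npy = write_npy(part, main),
      txt = .write_txt_matrix(part, main),
      mat = write_mat5(list(features = part), main),
      hdf5 = .write_hdf5(part, main)
    )
    paths[i] <- main
  }
  invisible(paths)
}

#' Merge saved splits back into one feature matrix
#'
#' Looks for `features_<i>_of_<k>` files of the given format under
#' `out_path`, checks completeness, and concatenates the parts in order.
#'
#' @param out_path directory holding split files.
#' @param file_format one of `"npy"`, `"txt"`, `"mat"`, `"hdf5"`.
#' @return the merged numeric matrix.
#' @export
merge_features <- function(out_path, file_format = "npy") {
  .check_format(file_format)
  ext <- .format_ext(file_format)
  files <- list.files(out_path, pattern = paste0("^features_\\d+_of_\\d+\\.", ext, "$"))
  if (!length(files)) {
    nr_error("netrsa_completeness_error",
             sprintf("no %s split files found under '%s'", file_format, out_path))
  }
  ks <- unique(as.integer(sub(paste0("^features_\\d+_of_(\\d+)\\.", ext, "$"), "\\1", files)))
  if (length(ks) != 1L) {
    nr_error("netrsa_completeness_error",
             sprintf("mixed split counts under '%s': k = %s", out_path,
                     paste(sort(ks), collapse = ", ")))
  }
  k <- ks
  idx <- as.integer(sub(paste0("^features_(\\d+)_of_\\d+\\.", ext, "$"), "\\1", files))
  missing <- setdiff(seq_len(k), idx)
  if (length(missing)) {
    nr_error("netrsa_completeness_error",
             sprintf("missing split(s) %s of %d under '%s'",
                     paste(missing, collapse = ", "), k, out_path))
  }
  parts <- lapply(seq_len(k), function(i) {
    main <- file.path(out_path, paste0(.split_stem(i, k), ".", ext))
    switch(file_format,
      npy = read_npy(main),
      txt = .read_txt_matrix(main),
      mat = read_mat5(main)$features,
      hdf5 = {
        v <- rhdf5::h5read(main, "features")
        rhdf5::h5closeAll()
        v
      }
    )
  })
  do.call(rbind, parts)
}

#' Slice a 4-D activation tensor into per-image 2-D matrices
#'
#' Each image's `K x H x W` activation becomes one `K x (H*W)` matrix
#' (width varying fastest within a row), so a tensor can be stored in
#' formats restricted to 2-D. The returned dims record inverts the
#' operation.
#'
#' @param tensor `N x K x H x W` array or [activation_tensor()].
#' @return list with `slices` (list of `N` matrices) and `dims` (`N, K, H, W`).
#' @export
tensor_to_slices <- function(tensor) {
  values <- .values_of(tensor)
  d <- dim(values)
  if (length(d) != 4L) {
    nr_error("netrsa_shape_error", "tensor_to_slices() expects an N x K x H x W block")
  }
  slices <- lapply(seq_len(d[1]), function(i) {
    z <- values[i, , , , drop = TRUE]
    dim(z) <- d[2:4]
    m <- aperm(z, c(3, 2, 1))          # (W,H,K): W fastest within each row
    dim(m) <- c(d[3] * d[4], d[2])
    t(m)
  })
  list(slices = slices, dims = d)
}

#' Reassemble a tensor from [tensor_to_slices()] output
#'
#' @param slices list of `K x (H*W)` matrices.
#' @param dims integer vector `(N, K, H, W)`.
#' @return `N x K x H x W` array; exact inverse of the slicing.
#' @export
slices_to_tensor <- function(slices, dims) {
  if (length(dims) != 4L || length(slices) != dims[1]) {
    nr_error("netrsa_shape_error",
             sprintf("dims record %s does not match %d slices",
                     paste(dims, collapse = "x"), length(slices)))
  }
  out <- array(0, dim = dims)
  for (i in seq_along(slices)) {
    m <- slices[[i]]
    if (!identical(dim(m), c(as.integer(dims[2]), as.integer(dims[3] * dims[4])))) {
      nr_error("netrsa_shape_error",
               sprintf("slice %d has shape %s, expected %d x %d",
                       i, paste(dim(m), collapse = "x"), dims[2], dims[3] * dims[4]))
    }
    z <- t(m)
    dim(z) <- c(dims[4], dims[3], dims[2])
    out[i, , , ] <- aperm(z, c(3, 2, 1))
  }
  out
}
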
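# Image directory -> ordered, labeled, batched stream. Ordering is byte-wise
# codepoint order of the relative path (radix sort, C locale), identical on
# every platform, unless the user supplies an explicit file-name list.

.IMAGE_EXTENSIONS <- c(".eps", ".jpg", ".jpeg", ".png", ".PNG", ".tif", ".tiff")

.has_allowed_ext <- function(paths) {
  exts <- sub(".*(\\.[^.]+)$", "\\1", paths)
  exts %in% .IMAGE_EXTENSIONS
}

#' Input transform specification
#'
#' Resize the shorter side to `resize` pixels (bilinear), centre-crop to
#' `crop` x `crop`, then normalize each channel as `(x - mean) / std`. The
#' defaults are the canonical ImageNet preprocessing constants.
#'
#' @param resize shorter-side target in pixels.
#' @param crop centre-crop size in pixels; must not exceed `resize`.
#' @param mean,std per-channel normalization constants (length 3).
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(resize = 256L, crop = 224L,
                           mean = c(0.485, 0.456, 0.406),
                           std = c(0.229, 0.224, 0.225)) {
  if (crop > resize) {
    nr_error("netrsa_parameter_error",
             sprintf("crop (%d) must not exceed resize (%d)", crop, resize))
  }
  if (any(std <= 0)) nr_error("netrsa_parameter_error", "std must be positive")
  structure(list(resize = as.integer(resize), crop = as.integer(crop),
                 mean = mean, std = std),
            class = "transform_spec")
}

#' Scan an image directory into an ordered dataset
#'
#' Files may sit directly under `root` (flat layout) or in one level of class
#' sub-folders (`root/class/img.png`); sub-folder names become class labels,
#' with class indices assigned by sorted label order starting at 0. Flat
#' datasets get class index 0 throughout. Records are ordered by byte-wise
#' codepoint order of the relative path (digits before uppercase before
#' lowercase) — independent of the operating system's collation — or exactly
#' by `file_names` when that list is given.
#'
#' @param root directory containing images (extensions
#'   `.eps .jpg .jpeg .png .PNG .tif .tiff`).
#' @param file_names optional character vector of relative paths fixing the
#'   extraction order.
#' @param transform a [transform_spec()].
#' @param layout `"channels_first"` (batches `B x C x H x W`) or
#'   `"channels_last"` (`B x H x W x C`).
#' @return an object of class `image_dataset` with one record per image.
#' @export
scan_images <- function(root, file_names = NULL, transform = transform_spec(),
                        layout = c("channels_first", "channels_last")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) {
    nr_error("netrsa_input_error", sprintf("image root not found: '%s'", root))
  }
  all_files <- list.files(root, recursive = TRUE, full.names = FALSE)
  all_files <- all_files[.has_allowed_ext(all_files)]
  all_files <- all_files[vapply(strsplit(all_files, "/", fixed = TRUE), length, 1L) <= 2L]
  if (!length(all_files)) {
    nr_error("netrsa_input_error", sprintf("no images with allowed extensions under '%s'", root))
  }
  if (is.null(file_names)) {
    ordered <- sort(all_files, method = "radix")
  } else {
    missing <- setdiff(file_names, all_files)
    if (length(missing)) {
      nr_error("netrsa_input_error",
               sprintf("file list names missing image(s): %s", paste(missing, collapse = ", ")))
    }
    ordered <- file_names
  }
  in_folder <- grepl("/", ordered, fixed = TRUE)
  labels <- ifelse(in_folder, sub("/.*$", "", ordered), NA_character_)
  if (all(in_folder)) {
    classes <- sort(unique(labels), method = "radix")
    class_idx <- match(labels, classes) - 1L
  } else {
    classes <- character(0)
    class_idx <- rep(0L, length(ordered))
  }
  records <- data.frame(path = ordered, label = labels, class_index = class_idx,
                        position = seq_along(ordered) - 1L,
                        stringsAsFactors = FALSE)
  structure(list(root = root, records = records, classes = classes,
                 transform = transform, layout = layout),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset> %d images under '%s' (%s)\n",
              nrow(x$records), x$root,
              if (length(x$classes)) sprintf("%d classes", length(x$classes)) else "flat layout"))
  invisible(x)
}

#' @export
length.image_dataset <- function(x) nrow(x$records)

#' Decode one image record to an `H x W x C` block in `[0, 1]`
#'
#' RGB images give `C = 3`; grayscale is replicated to three identical
#' channels; an alpha channel is dropped.
#'
#' @param dataset an [scan_images()] dataset, or a directory root.
#' @param record a row of `dataset$records`, a relative path, or a record
#'   position (1-based row number).
#' @return `H x W x 3` numeric array with values in `[0, 1]`.
#' @export
load_image <- function(dataset, record) {
  root <- if (inherits(dataset, "image_dataset")) dataset$root else dataset
  rel <- if (is.character(record)) {
    record
  } else if (is.numeric(record)) {
    dataset$records$path[record]
  } else {
    record$path
  }
  path <- file.path(root, rel)
  ext <- tolower(sub(".*(\\.[^.]+)$", "\\1", rel))
  img <- tryCatch(
    switch(ext,
      ".png" = png::readPNG(path),
      ".jpg" = , ".jpeg" = jpeg::readJPEG(path),
      ".tif" = , ".tiff" = tiff::readTIFF(path),
      ".eps" = nr_error("netrsa_decode_error",
                        sprintf("cannot rasterize EPS input '%s': no rasterizer available", rel)),
      nr_error("netrsa_decode_error", sprintf("unsupported image extension for '%s'", rel))
    ),
    error = function(e) {
      if (inherits(e, "netrsa_error")) stop(e)
      nr_error("netrsa_decode_error", sprintf("failed to decode '%s': %s", rel, conditionMessage(e)))
    }
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 1L) {
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  } else if (dim(img)[3] >= 4L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

# Bilinear resample of an H x W x C block to th x tw, half-pixel-centre
# convention (src = (dst + 0.5) * scale - 0.5).
.bilinear_resize <- function(img, th, tw) {
  d <- dim(img); H <- d[1]; W <- d[2]; C <- d[3]
  if (th == H && tw == W) return(img)
  map_axis <- function(t, S) {
    src <- (seq_len(t) - 0.5) * (S / t) - 0.5
    src <- pmin(pmax(src, 0), S - 1)
    lo <- floor(src)
    list(lo = as.integer(lo) + 1L,
         hi = as.integer(pmin(lo + 1, S - 1)) + 1L,
         w = src - lo)
  }
  ay <- map_axis(th, H); ax <- map_axis(tw, W)
  out <- array(0, dim = c(th, tw, C))
  for (ch in seq_len(C)) {
    plane <- img[, , ch]
    top <- plane[ay$lo, ax$lo, drop = FALSE] * (1 - ax$w)[col(matrix(0, th, tw))] +
           plane[ay$lo, ax$hi, drop = FALSE] * ax$w[col(matrix(0, th, tw))]
    bot <- plane[ay$hi, ax$lo, drop = FALSE] * (1 - ax$w)[col(matrix(0, th, tw))] +
           plane[ay$hi, ax$hi, drop = FALSE] * ax$w[col(matrix(0, th, tw))]
    out[, , ch] <- top * (1 - ay$w) + bot * ay$w
  }
  out
}

#' Apply the input transform to a decoded image
#'
#' Resizes the shorter side, centre-crops, normalizes per channel, and
#' permutes to `C x H x W` unless `layout = "channels_last"`.
#'
#' @param image `H x W x C` block from [load_image()].
#' @param transform a [transform_spec()].
#' @param layout `"channels_first"` or `"channels_last"`.
#' @return `C x crop x crop` (channels first) or `crop x crop x C` block.
#' @export
apply_transforms <- function(image, transform = transform_spec(),
                             layout = c("channels_first", "channels_last")) {
  layout <- match.arg(layout)
  d <- dim(image); H <- d[1]; W <- d[2]
  scale <- transform$resize / min(H, W)
  th <- max(transform$resize, as.integer(round(H * scale)))
  tw <- max(transform$resize, as.integer(round(W * scale)))
  resized <- .bilinear_resize(image, th, tw)
  if (transform$crop > th || transform$crop > tw) {
    nr_error("netrsa_parameter_error",
             sprintf("crop %d exceeds resized image %dx%d", transform$crop, th, tw))
  }
  y0 <- (th - transform$crop) %/% 2L
  x0 <- (tw - transform$crop) %/% 2L
  cropped <- resized[y0 + seq_len(transform$crop), x0 + seq_len(transform$crop), , drop = FALSE]
  for (ch in seq_len(dim(cropped)[3])) {
    cropped[, , ch] <- (cropped[, , ch] - transform$mean[ch]) / transform$std[ch]
  }
  if (layout == "channels_first") aperm(cropped, c(3, 1, 2)) else cropped
}

#' Split a dataset into ordered mini-batches
#'
#' Batches preserve dataset order; the last batch may be smaller; no
#' shuffling ever happens. Each batch holds the transformed image block
#' (`B x C x H x W`, or `B x H x W x C` for `channels_last`), the integer
#' class labels, and the 0-based record positions.
#'
#' @param dataset an [scan_images()] dataset.
#' @param batch_size number of images per forward pass (`B >= 1`).
#' @return list of `batch` objects (fields `data`, `labels`, `positions`).
#' @export
batch_iterator <- function(dataset, batch_size = 32L) {
  if (!is_count(batch_size)) nr_error("netrsa_range_error", "batch_size must be a positive integer")
  n <- nrow(dataset$records)
  starts <- seq(1L, n, by = as.integer(batch_size))
  lapply(starts, function(s) {
    idx <- s:min(s + batch_size - 1L, n)
    blocks <- lapply(idx, function(i) {
      apply_transforms(load_image(dataset, dataset$records[i, ]),
                       dataset$transform, dataset$layout)
    })
    d <- dim(blocks[[1]])
    data <- array(0, dim = c(length(idx), d))
    for (j in seq_along(blocks)) {
      data[j, , , ] <- blocks[[j]]
    }
    structure(list(data = data,
                   labels = dataset$records$class_index[idx],
                   positions = dataset$records$position[idx],
                   layout = dataset$layout),
              class = "batch")
  })
}

#' Write the order-record file
#'
#' Writes `file_names.txt` under `out_path`: one relative image path per
#' line, in extraction order, UTF-8 with LF line endings. Row `i` of any
#' feature matrix extracted from the dataset corresponds to line `i`.
#'
#' @param dataset an [scan_images()] dataset.
#' @param out_path output directory (created if needed).
#' @return path of the written file, invisibly.
#' @export
write_order_record <- function(dataset, out_path) {
  if (!dir.exists(out_path) && !dir.create(out_path, recursive = TRUE, showWarnings = FALSE)) {
    nr_error("netrsa_io_error", sprintf("cannot create output directory '%s'", out_path))
  }
  path <- file.path(out_path, "file_names.txt")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(enc2utf8(dataset$records$path), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
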
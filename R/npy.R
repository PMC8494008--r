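# Minimal NumPy .npy (format version 1.0) reader/writer for double-precision
# arrays. Only the subset this package emits is supported: dtype '<f8',
# C-contiguous, any number of dimensions.

#' Write a numeric array to a NumPy `.npy` file
#'
#' Writes double precision, little-endian, C-order (last index fastest), format
#' version 1.0. Matrices and higher-dimensional arrays keep their shape;
#' vectors are written as 1-D.
#'
#' @param x numeric vector, matrix or array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  if (!is.numeric(x)) nr_error("netrsa_format_error", "write_npy() needs a numeric array")
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  # C order = last index fastest; R stores first index fastest, so reverse axes
  xc <- if (length(shape) > 1L) aperm(x, rev(seq_along(shape))) else x
  shape_str <- if (length(shape) == 1L) {
    sprintf("(%d,)", shape)
  } else {
    sprintf("(%s)", paste(shape, collapse = ", "))
  }
  dict <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }", shape_str)
  # header (magic + version + length field + dict + '\n') padded to 64 bytes
  base_len <- 6L + 2L + 2L + nchar(dict, type = "bytes") + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header, type = "bytes")), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.double(xc), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NumPy `.npy` file written by [write_npy()]
#'
#' Supports `<f8` (double) and `<i8`/`<i4` integer arrays in either memory
#' order.
#'
#' @param path file path.
#' @return numeric vector, matrix or array with the stored shape.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    nr_error("netrsa_format_error", sprintf("'%s' is not an npy file", path))
  }
  ver <- readBin(con, "raw", 2)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  if (length(shape) == 0L) shape <- integer(0)
  n <- if (length(shape)) prod(shape) else 1L
  x <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<i4" = as.double(readBin(con, "integer", n, size = 4, endian = "little")),
    nr_error("netrsa_format_error", sprintf("unsupported npy dtype '%s'", descr))
  )
  if (length(shape) <= 1L) return(x)
  if (fortran) {
    array(x, dim = shape)
  } else {
    aperm(array(x, dim = rev(shape)), rev(seq_along(shape)))
  }
}
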
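# Minimal MATLAB Level-5 MAT-file writer/reader for uncompressed double
# arrays. Covers exactly the subset this package emits: named numeric arrays
# of any dimensionality, column-major, little-endian.

.mat5_pad <- function(n) (8L - n %% 8L) %% 8L

.mat5_write_element <- function(con, name, x) {
  dims <- if (is.null(dim(x))) c(1L, length(x)) else dim(x)
  if (length(dims) == 1L) dims <- c(1L, dims)
  name_raw <- charToRaw(name)
  n_data <- 8L * length(x)
  nbytes <- 16L +                                     # array flags
    8L + 4L * length(dims) + .mat5_pad(4L * length(dims)) +
    8L + length(name_raw) + .mat5_pad(length(name_raw)) +
    8L + n_data + .mat5_pad(n_data)
  writeBin(c(14L, nbytes), con, size = 4, endian = "little")        # miMATRIX
  writeBin(c(6L, 8L), con, size = 4, endian = "little")             # miUINT32
  writeBin(c(6L, 0L), con, size = 4, endian = "little")             # mxDOUBLE_CLASS, nzmax
  writeBin(c(5L, 4L * length(dims)), con, size = 4, endian = "little")  # miINT32
  writeBin(as.integer(dims), con, size = 4, endian = "little")
  writeBin(raw(.mat5_pad(4L * length(dims))), con)
  writeBin(c(1L, length(name_raw)), con, size = 4, endian = "little")   # miINT8
  writeBin(name_raw, con)
  writeBin(raw(.mat5_pad(length(name_raw))), con)
  writeBin(c(9L, n_data), con, size = 4, endian = "little")         # miDOUBLE
  writeBin(as.double(x), con, size = 8, endian = "little")
  writeBin(raw(.mat5_pad(n_data)), con)
}

#' Write numeric arrays to a MATLAB Level-5 `.mat` file
#'
#' @param vars named list of numeric vectors/matrices/arrays.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  if (is.null(names(vars)) || any(!nzchar(names(vars)))) {
    nr_error("netrsa_format_error", "write_mat5() needs a fully named list")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by netrsa on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  desc_raw <- charToRaw(desc)
  header <- raw(116)
  header[seq_along(desc_raw)] <- desc_raw
  header[(length(desc_raw) + 1):116] <- as.raw(0x20)
  writeBin(header, con)
  writeBin(raw(8), con)                                   # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100 LE
  writeBin(charToRaw("IM"), con)                          # endian indicator
  for (nm in names(vars)) .mat5_write_element(con, nm, vars[[nm]])
  invisible(path)
}

#' Read a `.mat` file written by [write_mat5()]
#'
#' Supports uncompressed little-endian double arrays only.
#'
#' @param path file path.
#' @return named list of numeric arrays.
#' @export
read_mat5 <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 124)
  endian_tag <- rawToChar(readBin(con, "raw", 4)[3:4])
  if (!identical(endian_tag, "IM")) {
    nr_error("netrsa_format_error", sprintf("'%s' is not a little-endian MAT-5 file", path))
  }
  out <- list()
  pos <- 128
  while (pos < sz) {
    tag <- readBin(con, "integer", 2, size = 4, endian = "little")
    if (tag[1] != 14L) {
      nr_error("netrsa_format_error",
               sprintf("unsupported MAT element type %d (compressed files are not supported)", tag[1]))
    }
    readBin(con, "integer", 4, size = 4, endian = "little")   # array flags
    dtag <- readBin(con, "integer", 2, size = 4, endian = "little")
    dims <- readBin(con, "integer", dtag[2] / 4L, size = 4, endian = "little")
    readBin(con, "raw", .mat5_pad(dtag[2]))
    ntag <- readBin(con, "integer", 2, size = 4, endian = "little")
    nhigh <- bitwShiftR(ntag[1], 16L)
    if (nhigh != 0L) {
      # small data element: length in the upper 16 bits of the first word
      name <- rawToChar(head(writeBin(ntag[2], raw(), size = 4, endian = "little"), nhigh))
    } else {
      name <- rawToChar(readBin(con, "raw", ntag[2]))
      readBin(con, "raw", .mat5_pad(ntag[2]))
    }
    vtag <- readBin(con, "integer", 2, size = 4, endian = "little")
    if (vtag[1] != 9L) {
      nr_error("netrsa_format_error", sprintf("unsupported MAT data type %d", vtag[1]))
    }
    n <- vtag[2] / 8L
    x <- readBin(con, "double", n, size = 8, endian = "little")
    readBin(con, "raw", .mat5_pad(vtag[2]))
    out[[name]] <- if (length(dims) == 2L && dims[1] == 1L) x else array(x, dim = dims)
    pos <- pos + 8 + tag[2]
  }
  out
}
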
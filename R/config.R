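# Workflow configuration: the variables that drive the extraction pipeline
# (root, model_name, pretrained, batch_size, module_name, out_path,
# file_format, device, layout, flatten_acts, seed), validated and defaulted
# in one place.

.MODULE_GRAMMAR <- "^[A-Za-z_][A-Za-z0-9_]*(\\.[A-Za-z0-9_]+)*$"

#' Validate and default an extraction configuration
#'
#' Takes a raw key-value mapping (named list) and returns a fully defaulted,
#' validated `extraction_config`. Required keys: `root` and `model_name`.
#' Defaults: `batch_size` 32 (a good trade-off between speed and memory for
#' users not tuning for throughput), `file_format` `"npy"`, `device`
#' `"cpu"`, `pretrained` `FALSE`, `layout` `"channels_first"`,
#' `flatten_acts` `TRUE`, `seed` 0. Validating an already-valid config is a
#' no-op (idempotent).
#'
#' `device = "gpu"` is accepted for interface compatibility but falls back
#' to CPU with a warning: the reference engine computes identical results on
#' either. `pretrained = TRUE` requires `weights`, a path to a local HDF5
#' weights archive; nothing is ever downloaded.
#'
#' @param raw named list (or `extraction_config`) of settings.
#' @return an object of class `extraction_config`.
#' @export
validate_config <- function(raw) {
  if (inherits(raw, "extraction_config")) raw <- unclass(raw)
  if (!is.list(raw)) nr_error("netrsa_config_error", "config must be a named list")
  known <- c("root", "model_name", "pretrained", "batch_size", "module_name",
             "out_path", "file_format", "device", "layout", "flatten_acts",
             "seed", "weights")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    nr_error("netrsa_config_error",
             sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (req in c("root", "model_name")) {
    if (is.null(raw[[req]])) {
      nr_error("netrsa_config_error", sprintf("config requires '%s'", req))
    }
  }
  cfg <- list(
    root = as.character(raw$root),
    model_name = as.character(raw$model_name),
    pretrained = isTRUE(raw$pretrained) || identical(raw$pretrained, "true"),
    batch_size = raw$batch_size %||% 32L,
    module_name = raw$module_name %||% NULL,
    out_path = raw$out_path %||% NULL,
    file_format = as.character(raw$file_format %||% "npy"),
    device = as.character(raw$device %||% "cpu"),
    layout = as.character(raw$layout %||% "channels_first"),
    flatten_acts = isTRUE(raw$flatten_acts) || identical(raw$flatten_acts, "true"),
    seed = raw$seed %||% 0L,
    weights = raw$weights %||% NULL
  )
  if (!dir.exists(cfg$root)) {
    nr_error("netrsa_input_error", sprintf("image root not found: '%s'", cfg$root))
  }
  bs <- suppressWarnings(as.numeric(cfg$batch_size))
  if (is.na(bs) || bs != as.integer(bs) || bs < 1) {
    nr_error("netrsa_range_error",
             sprintf("batch_size must be a positive integer, got '%s'",
                     as.character(cfg$batch_size)))
  }
  cfg$batch_size <- as.integer(bs)
  .check_format(cfg$file_format)
  if (!cfg$device %in% c("cpu", "gpu")) {
    nr_error("netrsa_config_error",
             sprintf("device must be 'cpu' or 'gpu', got '%s'", cfg$device))
  }
  if (cfg$device == "gpu") {
    warning("device = 'gpu' is not available in the reference engine; falling back to cpu")
    cfg$device <- "cpu"
  }
  if (!cfg$layout %in% c("channels_first", "channels_last")) {
    nr_error("netrsa_config_error",
             sprintf("layout must be 'channels_first' or 'channels_last', got '%s'", cfg$layout))
  }
  if (!is.null(cfg$module_name) && !grepl(.MODULE_GRAMMAR, cfg$module_name)) {
    nr_error("netrsa_config_error",
             sprintf("module_name '%s' does not match <leaf>[.<child>]* grammar", cfg$module_name))
  }
  sd <- suppressWarnings(as.numeric(cfg$seed))
  if (is.na(sd) || sd < 0 || sd != as.integer(sd)) {
    nr_error("netrsa_range_error", "seed must be a non-negative integer")
  }
  cfg$seed <- as.integer(sd)
  if (cfg$pretrained && is.null(cfg$weights)) {
    nr_error("netrsa_weights_error",
             "pretrained = TRUE requires 'weights', a local weights-archive path")
  }
  structure(cfg, class = "extraction_config")
}

#' @export
print.extraction_config <- function(x, ...) {
  cat("<extraction_config>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s: %s\n", nm, as.character(x[[nm]])))
  }
  invisible(x)
}

#' Read a flat `key=value` configuration file
#'
#' One `key=value` pair per line; blank lines and `#` comments are ignored.
#' Values are passed to [validate_config()] untouched (booleans as
#' `true`/`false`).
#'
#' @param path file path.
#' @return named list suitable for [validate_config()].
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) {
    nr_error("netrsa_input_error", sprintf("config file not found: '%s'", path))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) {
      nr_error("netrsa_config_error", sprintf("malformed config line: '%s'", ln))
    }
    out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}
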
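#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist hclust cutree as.dist median rnorm runif
#' @importFrom utils head tail
NULL

# Condition helpers: every user-facing error carries a subclass so the CLI can
# map failures to one-line diagnostics.
nr_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "netrsa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_character <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

# Polynomial string hash over UTF-8 bytes, kept inside 2^31 so the result can
# seed R's Mersenne-Twister on any platform.
.nr_hash_string <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  h
}

# Derive a 32-bit seed from (seed, key); distinct keys decorrelate streams so
# every module's weights depend only on the global seed and its own path.
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 2147483647 * 2654435 + .nr_hash_string(key)) %% 2147483647)
}

# Run `expr` under a local RNG stream keyed by (seed, key), restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, key))
  expr
}
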
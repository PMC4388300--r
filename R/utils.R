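# Internal helpers shared across modules.

#' Derive a reproducible child seed from a top-level seed and a stream name
#'
#' Each randomised operation in the package draws from its own named
#' substream so that running stages in a different order (or in parallel)
#' does not change any stage's results. The child seed is a deterministic
#' 31-bit hash of the parent seed and the stream label.
#'
#' @param seed Integer top-level seed.
#' @param name Character stream label, e.g. `"bootstrap"`.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "bootstrap")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  # FNV-1a style accumulation over the label bytes, folded with the seed,
  # kept in double precision below 2^31 (exact integer arithmetic range)
  h <- (as.double(seed) %% 2147483647) + 1
  for (b in as.integer(charToRaw(name))) {
    h <- (h * 16777619 + b) %% 2147483647
  }
  as.integer(h)
}

# run expr with a locally-set RNG seed, restoring outer RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# sample() without the scalar-x surprise: pick k elements of the vector x
sample_of <- function(x, k) {
  if (length(x) == 1L && k == 1L) x else sample(x, k)
}

# stop with a classed condition (config/data errors carry their own class)
fatal <- function(msg, class = "divscan_error", ...) {
  rlang::abort(msg, class = class, ...)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
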
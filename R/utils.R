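# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream; NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# all unordered sample pairs i < j as a two-column data frame of ids
pair_grid <- function(ids) {
  n <- length(ids)
  stopifnot(n >= 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

lower_tri <- function(m) m[lower.tri(m)]

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# derive a stream-specific 32-bit seed from a master seed (stays < 2^31)
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
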
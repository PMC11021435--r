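#' @keywords internal
"_PACKAGE"

# Clamp intensities to the valid [0, 1] range.
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Run `expr` under a temporary RNG state seeded with `seed`; if `seed` is
# NULL the current global RNG stream is used (and advanced).
with_seed_or_global <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image))) {
    stop(sprintf("`%s` must be a finite numeric matrix", arg), call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 1) {
    stop(sprintf("`%s` must have intensities in [0, 1]", arg), call. = FALSE)
  }
  invisible(image)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

# Stable per-purpose seed derivation so that one user seed drives many
# independent streams without collisions; keeps results in 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% 2147483587L
}
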
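# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index; stays in
# [0, 2^31 - 2] so it is always a valid integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 69069 + as.double(stream) * 7907) %% 2147483647)
}

# 2D inverse FFT with the usual 1/N normalization (base fft() is unnormalized).
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

is_image <- function(x) is.matrix(x) && is.numeric(x) && all(dim(x) >= 1L)
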
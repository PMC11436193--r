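# Shared fixtures and independent oracles used across test files.

# A small configuration that keeps fits cheap.
tiny_config <- function(shape = c(8L, 8L), Nscale = 2L, Nori = 4L) {
  lg_config(Nscale = Nscale, Nori = Nori, image_shape = shape)
}

sparse_feat <- function(index, count, length) {
  structure(list(index = index, count = count, length = length),
            class = "sparse_feature")
}

# Brute-force circular spatial convolution with a filter's complex
# spatial-domain kernel; real part. Independent of the package's
# frequency-domain path.
spatial_conv_oracle <- function(image, transfer) {
  n1 <- nrow(image); n2 <- ncol(image)
  ker <- fft(transfer, inverse = TRUE) / (n1 * n2)
  out <- matrix(0, n1, n2)
  for (y in seq_len(n1)) for (x in seq_len(n2)) {
    s <- 0 + 0i
    for (v in seq_len(n1)) for (u in seq_len(n2)) {
      s <- s + image[v, u] * ker[((y - v) %% n1) + 1, ((x - u) %% n2) + 1]
    }
    out[y, x] <- Re(s)
  }
  out
}

# Independent per-pixel argmax-orientation histogram (fractions).
argmax_hist_oracle <- function(maps) {
  n_ori <- length(maps)
  arr <- simplify2array(maps)                 # r x c x Nori
  am <- apply(arr, c(1, 2), which.max)        # first max = lowest ori index
  tabulate(as.vector(am), nbins = n_ori) / (nrow(am) * ncol(am))
}

# Plane-wave grating whose wave vector sits at angle `theta` with
# frequency `f` cycles/pixel.
grating <- function(shape, f, theta, phase = 0.7) {
  Y <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  X <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  0.5 + 0.4 * sin(2 * pi * f * (X * cos(theta) + Y * sin(theta)) + phase)
}

random_images <- function(n, shape, seed = 99) {
  set.seed(seed)
  replicate(n, matrix(runif(prod(shape)), shape[1], shape[2]),
            simplify = FALSE)
}
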
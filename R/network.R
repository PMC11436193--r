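#' Fit the two-layer Log-Gabor convolutional feature extractor
#'
#' Trains the unsupervised vein-feature network: a candidate bank of
#' `Nscale x Nori` Log-Gabor filters is built, the per-scale orientation
#' selection of [select_orientations()] fixes which orientations survive at
#' each scale (the diamond structure), and the retained filters become the
#' kernels of two consecutive convolutional layers. No labels are used at
#' any point; "training" is purely the response-counting selection. Feature
#' extraction then runs layer 1 (K1 filters), layer 2 (K2 filters applied
#' to every layer-1 map), binary hashing of each parent's K2 signed maps
#' into one integer-coded map, and block-wise histogram pooling into a
#' sparse vector of conceptual length `2^K2 * K1 * B`.
#'
#' By default the second layer reuses the first layer's selected filters
#' (`K1 = K2`). With `relearn_layer2 = TRUE` the selection is repeated on
#' the layer-1 response maps of the training images.
#'
#' @param train_images list of numeric matrices (grayscale ROIs in
#'   `[0, 1]`), all at `config$image_shape`.
#' @param config an [lg_config()].
#' @param per_scale_counts orientations kept per scale; the default
#'   `c(2, 7, 7, 2)` keeps few orientations at the extreme scales and many
#'   at the middle ones.
#' @param block_shape `c(rows, cols)` of the non-overlapping histogram
#'   blocks; must divide the image shape. Default 8x8 blocks, i.e. B = 16
#'   blocks on a 32x32 ROI.
#' @param relearn_layer2 if `TRUE`, re-run orientation selection on the
#'   layer-1 maps for the second layer.
#' @return An object of class `"vfdcn"` with components `config`,
#'   `diamond` (layer-1 selection), `diamond2`, `bank1`, `bank2`, `K1`,
#'   `K2`, `block_shape`, `B`, `feature_length`.
#' @seealso [predict.vfdcn()], [evaluate_recognition()]
#' @examples
#' imgs <- replicate(4, matrix(runif(256), 16, 16), simplify = FALSE)
#' cfg <- lg_config(Nscale = 2, Nori = 4, image_shape = c(16, 16))
#' m <- vfdcn(imgs, cfg, per_scale_counts = c(1, 2), block_shape = c(8, 8))
#' f <- predict(m, imgs[[1]])
#' @export
vfdcn <- function(train_images, config = lg_config(),
                  per_scale_counts = c(2L, 7L, 7L, 2L),
                  block_shape = c(8L, 8L), relearn_layer2 = FALSE) {
  stopifnot(inherits(config, "lg_config"))
  if (is.matrix(train_images)) train_images <- list(train_images)
  if (!length(train_images)) stop("empty training set", call. = FALSE)
  shp <- config$image_shape
  ok <- vapply(train_images, function(im) is_image(im) && all(dim(im) == shp),
               logical(1))
  if (!all(ok)) stop("all training images must match config$image_shape",
                     call. = FALSE)
  block_shape <- as.integer(block_shape)
  if (any(shp %% block_shape != 0L))
    stop("'block_shape' must divide the image shape exactly", call. = FALSE)

  cand <- build_bank(config)
  diamond <- select_orientations(train_images, config, per_scale_counts,
                                 bank = cand)
  bank1 <- build_bank(config, diamond$angles)
  if (relearn_layer2) {
    l1maps <- list()
    for (img in train_images) {
      F <- stats::fft(img)
      for (f in bank1$filters)
        l1maps[[length(l1maps) + 1L]] <- Re(ifft2(F * f$transfer))
    }
    diamond2 <- select_orientations(l1maps, config, per_scale_counts,
                                    bank = cand)
    bank2 <- build_bank(config, diamond2$angles)
  } else {
    diamond2 <- diamond
    bank2 <- bank1
  }
  K1 <- length(bank1$filters)
  K2 <- length(bank2$filters)
  if (K1 < 1L || K2 < 1L) stop("selection retained no filters", call. = FALSE)
  B <- prod(shp %/% block_shape)
  structure(list(config = config, per_scale_counts = as.integer(per_scale_counts),
                 diamond = diamond, diamond2 = diamond2,
                 bank1 = bank1, bank2 = bank2, K1 = K1, K2 = K2,
                 block_shape = block_shape, B = B,
                 feature_length = 2^K2 * K1 * B),
            class = "vfdcn")
}

check_trained <- function(model) {
  if (!inherits(model, "vfdcn") || is.null(model$bank1) || is.null(model$bank2))
    stop("model is not a trained 'vfdcn' object", call. = FALSE)
}

#' Log-Gabor convolution of an image with one filter
#'
#' Frequency-domain (circular) filtering: the real part of
#' `IFFT(FFT(image) * transfer)`. Output has the input's shape; constant
#' images map to zero because the filters pass no DC.
#'
#' @param image numeric matrix.
#' @param filter an `"lg_filter"` whose transfer matches `dim(image)`.
#' @return Signed numeric matrix, same shape as `image`.
#' @export
loggabor_conv <- function(image, filter) {
  stopifnot(is_image(image), inherits(filter, "lg_filter"))
  if (!all(dim(image) == dim(filter$transfer)))
    stop("image and filter shapes differ", call. = FALSE)
  Re(ifft2(stats::fft(image) * filter$transfer))
}

#' First convolutional layer
#'
#' @param image ROI matrix at the model's input shape.
#' @param model a trained [vfdcn()] model.
#' @return List of `K1` signed response maps.
#' @export
layer1 <- function(image, model) {
  check_trained(model)
  if (!all(dim(image) == model$config$image_shape))
    stop("image shape does not match the model input", call. = FALSE)
  F <- stats::fft(image)
  lapply(model$bank1$filters, function(f) Re(ifft2(F * f$transfer)))
}

#' Second convolutional layer
#'
#' Applies each of the `K2` layer-2 filters to every layer-1 map, keeping
#' the grouping by parent map: element `j` of the result holds the `K2`
#' maps derived from layer-1 map `j` alone.
#'
#' @param maps list of layer-1 maps from [layer1()].
#' @param model a trained [vfdcn()] model.
#' @return List of length `K1`; each element a list of `K2` signed maps.
#' @export
layer2 <- function(maps, model) {
  check_trained(model)
  lapply(maps, function(m) {
    F <- stats::fft(m)
    lapply(model$bank2$filters, function(f) Re(ifft2(F * f$transfer)))
  })
}

#' Binary hashing of a stack of signed maps
#'
#' Thresholds each map with the Heaviside step (1 where strictly positive)
#' and combines the K2 binary maps with powers-of-two weights `2^(k-1)`
#' into one integer-coded map in `[0, 2^K2 - 1]`. Bit `k` follows the
#' supplied map order (the model's layer-2 filter order).
#'
#' @param maps list of equally-shaped signed numeric matrices.
#' @return Numeric matrix of integer codes.
#' @export
binary_hash <- function(maps) {
  if (!length(maps)) stop("no maps to hash", call. = FALSE)
  d <- dim(maps[[1]])
  code <- matrix(0, d[1], d[2])
  for (k in seq_along(maps)) {
    if (!all(dim(maps[[k]]) == d))
      stop("maps must share one shape", call. = FALSE)
    code <- code + 2^(k - 1) * (maps[[k]] > 0)
  }
  code
}

#' Block-wise histogram of an encoded map
#'
#' Partitions the integer-coded map into `B` non-overlapping blocks
#' (row-major block order), histograms each block over the code range
#' `0 .. 2^K2 - 1`, and concatenates the block histograms. The result is
#' returned sparsely since `2^K2` bins per block are mostly empty.
#'
#' @param encoded integer-coded matrix from [binary_hash()].
#' @param block_shape `c(rows, cols)`; must divide `dim(encoded)`.
#' @param K2 number of hash bits (fixes the bin range).
#' @return Object of class `"sparse_feature"`: list with `index` (1-based
#'   positions into the conceptual vector), `count`, `length`
#'   (`2^K2 * B`). Each block's counts sum to the block pixel count.
#' @export
blockwise_histogram <- function(encoded, block_shape, K2) {
  stopifnot(is_image(encoded))
  block_shape <- as.integer(block_shape)
  d <- dim(encoded)
  if (any(d %% block_shape != 0L))
    stop("'block_shape' must divide the map shape exactly", call. = FALSE)
  nb <- d %/% block_shape
  br <- (row(encoded) - 1L) %/% block_shape[1]
  bc <- (col(encoded) - 1L) %/% block_shape[2]
  block <- br * nb[2] + bc                      # 0-based, row-major blocks
  nbins <- 2^K2
  pos <- as.vector(block) * nbins + as.vector(encoded) + 1  # 1-based
  r <- rle(sort(pos))
  structure(list(index = r$values, count = r$lengths,
                 length = nbins * prod(nb)),
            class = "sparse_feature")
}

#' Extract the sparse feature vector of one ROI
#'
#' Runs the full forward pass: layer 1, layer 2 grouped by parent, binary
#' hashing per parent, block-wise histograms, and concatenation over the
#' `K1` encoded maps. The result is deterministic and its entries sum to
#' `K1 * rows * cols` (every pixel of every encoded map lands in exactly
#' one histogram bin).
#'
#' @param image ROI matrix at the model's input shape.
#' @param model a trained [vfdcn()] model.
#' @return A `"sparse_feature"` of conceptual length `2^K2 * K1 * B`.
#' @export
extract_feature <- function(image, model) {
  check_trained(model)
  if (!all(dim(image) == model$config$image_shape))
    stop("image shape does not match the model input", call. = FALSE)
  K2 <- model$K2
  nbins <- 2^K2
  seg_len <- nbins * model$B
  transfers2 <- lapply(model$bank2$filters, `[[`, "transfer")
  F0 <- stats::fft(image)
  idx <- list(); cnt <- list()
  for (j in seq_len(model$K1)) {
    m1 <- Re(ifft2(F0 * model$bank1$filters[[j]]$transfer))
    F1 <- stats::fft(m1)
    code <- matrix(0, nrow(image), ncol(image))
    for (k in seq_len(K2)) {
      code <- code + 2^(k - 1) * (Re(ifft2(F1 * transfers2[[k]])) > 0)
    }
    h <- blockwise_histogram(code, model$block_shape, K2)
    idx[[j]] <- h$index + (j - 1) * seg_len
    cnt[[j]] <- h$count
  }
  structure(list(index = unlist(idx), count = unlist(cnt),
                 length = model$feature_length),
            class = "sparse_feature")
}

#' Extract features for new images
#'
#' @param object a trained [vfdcn()] model.
#' @param newdata a single ROI matrix or a list of them.
#' @param ... ignored.
#' @return A `"sparse_feature"` for a single matrix, otherwise a list of
#'   them.
#' @export
predict.vfdcn <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(extract_feature(newdata, object))
  lapply(newdata, extract_feature, model = object)
}

#' Euclidean distance between two sparse feature vectors
#'
#' Computed directly on the sparse representations (no densifying):
#' `sqrt(|f|^2 + |g|^2 - 2 f.g)` with the dot product over shared indices.
#'
#' @param f,g `"sparse_feature"` objects of equal conceptual length.
#' @return Nonnegative scalar distance.
#' @export
match_distance <- function(f, g) {
  stopifnot(inherits(f, "sparse_feature"), inherits(g, "sparse_feature"))
  if (f$length != g$length)
    stop("feature dimensions differ", call. = FALSE)
  m <- match(f$index, g$index)
  dot <- sum(f$count[!is.na(m)] * g$count[m[!is.na(m)]])
  d2 <- sum(f$count^2) + sum(g$count^2) - 2 * dot
  sqrt(max(d2, 0))
}

#' @export
print.vfdcn <- function(x, ...) {
  cat("Log-Gabor diamond convolutional feature extractor\n")
  cat(sprintf("  input: %d x %d; layers: K1 = %d, K2 = %d filters\n",
              x$config$image_shape[1], x$config$image_shape[2], x$K1, x$K2))
  cat(sprintf("  diamond structure: [%s] over %d candidate orientations\n",
              paste(x$per_scale_counts, collapse = ","), x$config$Nori))
  cat(sprintf("  pooling: %d x %d blocks (B = %d); feature length 2^%d * %d * %d = %s\n",
              x$block_shape[1], x$block_shape[2], x$B, x$K2, x$K1, x$B,
              format(x$feature_length, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
summary.vfdcn <- function(object, ...) {
  print(object)
  cat("\nLayer-1 selection weights (scale x orientation):\n")
  w <- object$diamond$weights
  dimnames(w) <- list(paste0("S", seq_len(nrow(w))),
                      sprintf("%.2f", object$diamond$candidate_angles))
  print(round(sweep(w, 1, pmax(rowSums(w), 1e-12), "/"), 3))
  cat("\nRetained angles per scale:\n")
  for (s in seq_along(object$diamond$angles))
    cat(sprintf("  S%d: %s\n", s,
                paste(sprintf("%.3f", object$diamond$angles[[s]]), collapse = ", ")))
  invisible(object)
}

#' @export
plot.vfdcn <- function(x, ...) plot(x$bank1, ...)
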
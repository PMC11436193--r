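#' Read a grayscale image rescaled to [0, 1]
#'
#' PNG is read with the png package; JPEG and TIFF via EBImage. Color
#' images are converted to luminance by channel averaging. BMP is not
#' supported by the available readers; convert such files to PNG first.
#'
#' @param path image file path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
    return(a)
  }
  if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    img <- EBImage::readImage(path)
    if (EBImage::colorMode(img) != 0) img <- EBImage::channel(img, "gray")
    a <- t(EBImage::imageData(img))       # EBImage stores x (cols) first
    if (length(dim(a)) == 3L) a <- a[, , 1]
    return(pmin(pmax(a, 0), 1))
  }
  stop("unsupported image format: .", ext, " (use PNG/JPEG/TIFF)", call. = FALSE)
}

# The eight 3x3 Kirsch compass masks (coefficients 5 / -3), one per
# principal direction.
kirsch_masks <- function() {
  base <- matrix(c(5, 5, 5, -3, 0, -3, -3, -3, -3), 3, 3, byrow = TRUE)
  rot <- function(m) {
    # rotate the ring of 8 neighbours one step clockwise
    ring_idx <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3), c(3, 3),
                      c(3, 2), c(3, 1), c(2, 1))
    vals <- m[ring_idx]
    out <- m
    out[ring_idx] <- vals[c(8, 1:7)]
    out
  }
  masks <- vector("list", 8)
  masks[[1]] <- base
  for (i in 2:8) masks[[i]] <- rot(masks[[i - 1]])
  masks
}

# 3x3 correlation with reflective boundary.
conv3_reflect <- function(image, mask) {
  r <- nrow(image); c <- ncol(image)
  pad <- rbind(image[1, , drop = FALSE], image, image[r, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, c, drop = FALSE])
  out <- matrix(0, r, c)
  for (dy in -1:1) for (dx in -1:1) {
    w <- mask[dy + 2, dx + 2]
    if (w != 0)
      out <- out + w * pad[(2 + dy):(r + 1 + dy), (2 + dx):(c + 1 + dx)]
  }
  out
}

#' Kirsch compass edge gradient
#'
#' Per-pixel maximum response over the eight 3x3 Kirsch compass masks,
#' with reflective image borders. The Kirsch operator balances weak-edge
#' sensitivity against false edges better than simple first-difference
#' operators, which is why it anchors the ROI localization.
#'
#' @param image numeric matrix.
#' @return Nonnegative gradient magnitude matrix, same shape.
#' @export
kirsch_gradient <- function(image) {
  stopifnot(is_image(image))
  masks <- kirsch_masks()
  out <- conv3_reflect(image, masks[[1]])
  for (i in 2:8) out <- pmax(out, conv3_reflect(image, masks[[i]]))
  pmax(out, 0)
}

#' Three-level dynamic threshold of a gradient map
#'
#' Binarizes the gradient at `mu + k * sigma` of its value distribution,
#' the three levels `k = 1, 2, 3` forming nested edge sets. When `k` is
#' not given, the smallest level whose edge density falls at or below
#' `density_ceiling` is chosen (falling back to `k = 3`), so noisier
#' images automatically receive a stricter threshold.
#'
#' @param gradient numeric matrix from [kirsch_gradient()].
#' @param k optional fixed level in `1:3`.
#' @param density_ceiling maximum acceptable fraction of edge pixels for
#'   the automatic level choice (default 0.1).
#' @return Logical edge matrix with attribute `"k"` (the level used).
#' @export
threshold_3sigma <- function(gradient, k = NULL, density_ceiling = 0.1) {
  stopifnot(is_image(gradient))
  mu <- mean(gradient); sg <- stats::sd(as.vector(gradient))
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k > 3L) stop("'k' must be 1, 2 or 3", call. = FALSE)
    edges <- gradient > mu + k * sg
    attr(edges, "k") <- k
    return(edges)
  }
  for (kk in 1:3) {
    edges <- gradient > mu + kk * sg
    if (mean(edges) <= density_ceiling) break
  }
  attr(edges, "k") <- kk
  edges
}

#' Bilinear resize of an ROI
#'
#' Resizes to the target shape (bilinear, via EBImage) and clips to
#' `[0, 1]`. An input already at the target shape is returned unchanged.
#'
#' @param roi numeric matrix.
#' @param target_shape integer `c(rows, cols)`.
#' @return Matrix of the target shape, values in `[0, 1]`.
#' @export
resize_roi <- function(roi, target_shape = c(32L, 32L)) {
  stopifnot(is_image(roi))
  target_shape <- as.integer(target_shape)
  if (all(dim(roi) == target_shape)) return(roi)
  out <- EBImage::imageData(EBImage::resize(EBImage::as.Image(roi),
                                            w = target_shape[1],
                                            h = target_shape[2]))
  pmin(pmax(out, 0), 1)
}

#' Localize and standardize the finger ROI
#'
#' Finds the upper and lower finger boundaries from the thresholded Kirsch
#' edge map — the rows with the longest horizontal edge runs in the top and
#' bottom halves of the frame — then crops the interior band plus a
#' horizontal margin and resizes to the network input shape. When no
#' plausible boundary pair is found the full frame is used and a warning is
#' emitted. Datasets that ship pre-cropped ROIs should set `bypass = TRUE`,
#' which skips localization and only resizes.
#'
#' @param image raw grayscale matrix in `[0, 1]`.
#' @param target_shape network input shape, default 32x32.
#' @param bypass if `TRUE`, treat the input as an already-cropped ROI.
#' @param margin horizontal margin cropped from each side, as a fraction
#'   of the width.
#' @param density_ceiling passed to [threshold_3sigma()].
#' @return Matrix of `target_shape` with attribute `"crop"`
#'   (`c(row0, row1, col0, col1)` of the crop box, or `"provided"`).
#' @export
extract_roi <- function(image, target_shape = c(32L, 32L), bypass = FALSE,
                        margin = 0.05, density_ceiling = 0.1) {
  stopifnot(is_image(image))
  if (bypass) {
    out <- resize_roi(image, target_shape)
    attr(out, "crop") <- "provided"
    return(out)
  }
  edges <- threshold_3sigma(kirsch_gradient(image), density_ceiling = density_ceiling)
  runlen <- apply(edges, 1, function(rw) {
    r <- rle(rw); m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  r <- nrow(image); c <- ncol(image)
  top_half <- seq_len(r %/% 2)
  bot_half <- (r %/% 2 + 1):r
  top <- if (any(runlen[top_half] > 0)) which.max(runlen[top_half]) else NA
  bot <- if (any(runlen[bot_half] > 0))
    bot_half[which.max(runlen[bot_half])] else NA
  cm <- max(1L, round(margin * c))
  if (is.na(top) || is.na(bot) || bot - top < 4L) {
    warning("finger boundaries not found; using the full frame")
    box <- c(1L, r, 1L, c)
  } else {
    box <- c(top + 1L, bot - 1L, cm, c - cm + 1L)
  }
  crop <- image[box[1]:box[2], box[3]:box[4], drop = FALSE]
  out <- resize_roi(crop, target_shape)
  attr(out, "crop") <- box
  out
}
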
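#' Orientation power maps at one scale
#'
#' Filters an ROI with every candidate orientation at a given scale by
#' frequency-domain multiplication and returns the absolute value of the
#' real part of each filtered image (the "power map" used by the
#' orientation-selection statistics).
#'
#' @param image numeric matrix matching the bank's grid shape.
#' @param bank an `"lg_bank"` (typically the full candidate bank).
#' @param scale_index scale whose orientations are evaluated.
#' @return Object of class `"lg_power_maps"`: list with `maps` (list of
#'   nonnegative matrices, one per orientation, in the bank's angle order),
#'   `theta0` (their angles) and `scale`.
#' @export
orientation_power_maps <- function(image, bank, scale_index) {
  stopifnot(inherits(bank, "lg_bank"), is_image(image))
  if (!all(dim(image) == bank$config$image_shape))
    stop("image shape does not match the filter bank grid", call. = FALSE)
  sel <- which(bank$index$scale == scale_index)
  if (!length(sel)) stop("no filters at this scale", call. = FALSE)
  F <- stats::fft(image)
  maps <- lapply(sel, function(i) {
    abs(Re(ifft2(F * bank$filters[[i]]$transfer)))
  })
  structure(list(maps = maps, theta0 = bank$index$theta0[sel],
                 scale = scale_index),
            class = "lg_power_maps")
}

#' Sort all pixel responses across orientation maps
#'
#' Enumerates every (orientation, row, col) response and sorts the records
#' by magnitude, descending. Ties keep enumeration order (orientation-major,
#' then row, then column), making the ordering fully deterministic.
#'
#' @param pow_maps an `"lg_power_maps"` object, or a plain list of
#'   equally-sized matrices.
#' @return data.frame with columns `value`, `row`, `col`, `ori`
#'   (orientation index), one row per response, sorted by `value`
#'   descending.
#' @export
sort_filter_response <- function(pow_maps) {
  maps <- if (inherits(pow_maps, "lg_power_maps")) pow_maps$maps else pow_maps
  if (!length(maps)) stop("empty power map set", call. = FALSE)
  r <- nrow(maps[[1]]); c <- ncol(maps[[1]])
  n <- r * c
  value <- unlist(lapply(maps, function(m) as.vector(t(m))), use.names = FALSE)
  row <- rep(rep(seq_len(r), each = c), times = length(maps))
  col <- rep(rep(seq_len(c), times = r), times = length(maps))
  ori <- rep(seq_along(maps), each = n)
  o <- order(-value, seq_along(value), method = "radix")  # stable descending
  data.frame(value = value[o], row = row[o], col = col[o], ori = ori[o])
}

#' Histogram of most-used orientations
#'
#' Walks the sorted response records from strongest to weakest; each pixel
#' contributes once, at its first appearance, to the orientation holding
#' its maximum magnitude. Counts are normalized to fractions, so the
#' weights sum to one.
#'
#' @param sorted data.frame from [sort_filter_response()].
#' @param Nori number of candidate orientations.
#' @param shape image shape `c(rows, cols)`.
#' @return Numeric vector of length `Nori`; nonnegative, sums to 1.
#' @export
count_most_used_ori <- function(sorted, Nori, shape) {
  stopifnot(is.data.frame(sorted), nrow(sorted) >= 1L)
  Nori <- as.integer(Nori)
  npix <- as.integer(shape[1]) * as.integer(shape[2])
  key <- (sorted$row - 1L) * as.integer(shape[2]) + sorted$col
  first <- !duplicated(key)
  counts <- tabulate(sorted$ori[first], nbins = Nori)
  counts / npix
}

#' Per-scale orientation selection (the diamond structure)
#'
#' For each scale independently, every training ROI is filtered with all
#' candidate orientations; per image, the fraction of pixels whose maximum
#' response falls on each orientation is accumulated (each image weighted
#' equally), and the `n_S` highest-weight orientations are retained. Ties
#' are broken by ascending orientation index. With many orientations kept
#' at the middle scales and few at the extremes, the retained counts trace
#' the "diamond" allocation.
#'
#' @param train_images list of numeric matrices, all at
#'   `config$image_shape`.
#' @param config an [lg_config()].
#' @param per_scale_counts integer vector of length `Nscale`; how many
#'   orientations to keep at each scale (each `<= Nori`, zeros allowed).
#' @param bank optional prebuilt candidate bank (rebuilt from `config`
#'   otherwise).
#' @return Object of class `"diamond_structure"`: list with `angles`
#'   (per-scale retained angles), `counts`, `weights` (Nscale x Nori matrix
#'   of accumulated normalized histograms) and `candidate_angles`.
#' @examples
#' imgs <- replicate(3, matrix(runif(64), 8, 8), simplify = FALSE)
#' cfg <- lg_config(Nscale = 2, Nori = 4, image_shape = c(8, 8))
#' select_orientations(imgs, cfg, c(1, 2))
#' @export
select_orientations <- function(train_images, config, per_scale_counts,
                                bank = NULL) {
  stopifnot(inherits(config, "lg_config"))
  if (!length(train_images)) stop("empty training set", call. = FALSE)
  per_scale_counts <- as.integer(per_scale_counts)
  if (length(per_scale_counts) != config$Nscale)
    stop("'per_scale_counts' must have one entry per scale", call. = FALSE)
  if (any(per_scale_counts < 0L) || any(per_scale_counts > config$Nori))
    stop("per-scale counts must lie in [0, Nori]", call. = FALSE)
  if (is.null(bank)) bank <- build_bank(config)
  cand <- orientation_angles(config$Nori)
  weights <- matrix(0, config$Nscale, config$Nori)
  for (s in seq_len(config$Nscale)) {
    acc <- numeric(config$Nori)
    for (img in train_images) {
      pm <- orientation_power_maps(img, bank, s)
      acc <- acc + count_most_used_ori(sort_filter_response(pm),
                                       config$Nori, dim(img))
    }
    weights[s, ] <- acc
  }
  angles <- vector("list", config$Nscale)
  for (s in seq_len(config$Nscale)) {
    n <- per_scale_counts[s]
    keep <- if (n > 0L)
      sort(order(-weights[s, ], seq_len(config$Nori), method = "radix")[seq_len(n)])
    else integer()
    angles[[s]] <- cand[keep]
  }
  structure(list(angles = angles, counts = per_scale_counts,
                 weights = weights, candidate_angles = cand),
            class = "diamond_structure")
}

#' @export
print.diamond_structure <- function(x, ...) {
  cat("Diamond orientation structure [",
      paste(x$counts, collapse = ","), "]\n", sep = "")
  for (s in seq_along(x$angles)) {
    cat(sprintf("  scale %d: %s\n", s,
                if (length(x$angles[[s]]))
                  paste(sprintf("%.3f", x$angles[[s]]), collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}
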
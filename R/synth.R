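#' Specification for the synthetic vein-image generator
#'
#' Describes a labeled dataset of synthetic near-infrared-like finger
#' images: dark curvilinear strokes (veins absorb the illumination) of
#' varying orientation and width on a brighter, noisy background. Each
#' class (finger identity) owns a fixed stroke geometry derived
#' deterministically from the class key and the global seed; samples of a
#' class differ only by a small rigid jitter and per-sample noise.
#'
#' @param n_classes number of identities.
#' @param samples_per_class images per identity.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param strokes_per_class inclusive range of stroke counts per class.
#' @param stroke_width inclusive range of stroke widths, pixels.
#' @param stroke_depth inclusive range of stroke darkening depth
#'   (intensity units).
#' @param background background intensity level.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param jitter_px maximum per-sample translation, pixels.
#' @param jitter_rad maximum per-sample rotation, radians.
#' @param orientation optional fixed stroke orientation (radians); `NULL`
#'   draws each stroke's orientation uniformly from `[0, pi)`.
#' @param seed global generator seed.
#' @return Validated list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_classes = 20L, samples_per_class = 6L,
                       image_shape = c(32L, 32L),
                       strokes_per_class = c(3L, 5L),
                       stroke_width = c(2, 6), stroke_depth = c(0.35, 0.55),
                       background = 0.75, noise_sigma = 0.04,
                       jitter_px = 1, jitter_rad = 0.06,
                       orientation = NULL, seed = 42L) {
  n_classes <- as.integer(n_classes)
  samples_per_class <- as.integer(samples_per_class)
  stopifnot(n_classes >= 1L, samples_per_class >= 1L,
            noise_sigma >= 0, jitter_px >= 0, jitter_rad >= 0,
            all(strokes_per_class >= 1L), all(stroke_width > 0),
            background > 0, background <= 1)
  structure(list(n_classes = n_classes, samples_per_class = samples_per_class,
                 image_shape = as.integer(image_shape),
                 strokes_per_class = as.integer(strokes_per_class),
                 stroke_width = stroke_width, stroke_depth = stroke_depth,
                 background = background, noise_sigma = noise_sigma,
                 jitter_px = jitter_px, jitter_rad = jitter_rad,
                 orientation = orientation, seed = as.integer(seed)),
            class = "synth_spec")
}

# Class geometry: a fixed set of slightly curved strokes, each defined by
# a center, orientation, curvature, length, width and depth.
class_geometry <- function(class_key, spec) {
  with_seed(derive_seed(spec$seed, class_key * 131L), {
    ns <- if (spec$strokes_per_class[1] == spec$strokes_per_class[2])
      spec$strokes_per_class[1]
    else sample(spec$strokes_per_class[1]:spec$strokes_per_class[2], 1)
    r <- spec$image_shape[1]; c <- spec$image_shape[2]
    lapply(seq_len(ns), function(i) {
      list(cy = stats::runif(1, 0.2 * r, 0.8 * r),
           cx = stats::runif(1, 0.2 * c, 0.8 * c),
           theta = if (is.null(spec$orientation))
             stats::runif(1, 0, pi) else spec$orientation,
           len = stats::runif(1, 0.7, 1.3) * max(r, c),
           curv = stats::runif(1, -0.15, 0.15),
           width = stats::runif(1, spec$stroke_width[1], spec$stroke_width[2]),
           depth = stats::runif(1, spec$stroke_depth[1], spec$stroke_depth[2]))
    })
  })
}

# Render one stroke as a soft-edged dark ridge: darkening falls off as a
# Gaussian of the distance to the stroke's center curve.
render_stroke <- function(canvas, st, dy, dx, drot, shape) {
  r <- shape[1]; c <- shape[2]
  th <- st$theta + drot
  t <- seq(-0.5, 0.5, length.out = 160) * st$len
  # quadratic bend perpendicular to the main direction
  off <- st$curv * (t / max(abs(t)))^2 * st$len * 0.5
  py <- st$cy + dy + t * sin(th) + off * cos(th)
  px <- st$cx + dx + t * cos(th) - off * sin(th)
  keep <- py > -2 & py < r + 2 & px > -2 & px < c + 2
  if (!any(keep)) return(canvas)
  py <- py[keep]; px <- px[keep]
  Y <- matrix(seq_len(r), r, c)
  X <- matrix(seq_len(c), r, c, byrow = TRUE)
  d2min <- matrix(Inf, r, c)
  for (i in seq_along(py)) {
    d2 <- (Y - py[i])^2 + (X - px[i])^2
    d2min <- pmin(d2min, d2)
  }
  s2 <- (st$width / 2)^2
  canvas - st$depth * exp(-d2min / (2 * s2))
}

#' Render one synthetic vein image
#'
#' Deterministic in `(class_key, sample_index, spec)`: the class geometry
#' is fixed by the class key and the global seed; the sample index drives
#' only the rigid jitter and the noise realization.
#'
#' @param class_key integer identity key (1-based).
#' @param sample_index integer sample number within the class (1-based).
#' @param spec a [synth_spec()].
#' @return Numeric matrix in `[0, 1]` of `spec$image_shape`.
#' @export
make_vein_image <- function(class_key, sample_index, spec) {
  stopifnot(inherits(spec, "synth_spec"))
  geom <- class_geometry(class_key, spec)
  shape <- spec$image_shape
  with_seed(derive_seed(spec$seed, class_key * 131L + sample_index * 17L + 1L), {
    dy <- stats::runif(1, -spec$jitter_px, spec$jitter_px)
    dx <- stats::runif(1, -spec$jitter_px, spec$jitter_px)
    drot <- stats::runif(1, -spec$jitter_rad, spec$jitter_rad)
    img <- matrix(spec$background, shape[1], shape[2])
    for (st in geom) img <- render_stroke(img, st, dy, dx, drot, shape)
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(prod(shape), 0, spec$noise_sigma),
                          shape[1], shape[2])
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a synthetic dataset in memory
#'
#' @param spec a [synth_spec()].
#' @return List with `images` (list of matrices), `labels`
#'   (`class_01` ...), `class_key`, `sample_index`.
#' @export
synth_images <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_classes * spec$samples_per_class
  images <- vector("list", n)
  labels <- character(n); ck <- si <- integer(n)
  i <- 0L
  for (k in seq_len(spec$n_classes)) {
    for (s in seq_len(spec$samples_per_class)) {
      i <- i + 1L
      images[[i]] <- make_vein_image(k, s, spec)
      labels[i] <- sprintf("class_%02d", k)
      ck[i] <- k; si[i] <- s
    }
  }
  list(images = images, labels = labels, class_key = ck, sample_index = si)
}

#' Write a synthetic dataset to disk
#'
#' Writes one PNG per sample in a class-per-folder layout
#' (`class_01/sample_01.png`, ...) plus a `manifest.json` recording the
#' generator specification. Regeneration with the same spec yields
#' byte-identical files.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
make_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create ", dir, call. = FALSE)
  paths <- character(0)
  for (k in seq_len(spec$n_classes)) {
    cls_dir <- file.path(dir, sprintf("class_%02d", k))
    dir.create(cls_dir, showWarnings = FALSE)
    for (s in seq_len(spec$samples_per_class)) {
      p <- file.path(cls_dir, sprintf("sample_%02d.png", s))
      png::writePNG(make_vein_image(k, s, spec), p)
      paths <- c(paths, p)
    }
  }
  sp <- unclass(spec)
  sp$orientation <- if (is.null(sp$orientation)) NA else sp$orientation
  jsonlite::write_json(sp, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
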
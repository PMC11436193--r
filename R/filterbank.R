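#' Log-Gabor filter-bank configuration
#'
#' Collects every scalar parameter needed to construct a multi-scale,
#' multi-orientation bank of 2D Log-Gabor filters in the polar frequency
#' domain. A Log-Gabor filter is a band-pass filter whose radial profile is
#' Gaussian on a logarithmic frequency axis; it has no DC component, so
#' constant image regions produce zero response.
#'
#' The defaults are the reference operating point for 32x32 finger-vein
#' ROIs: smallest wavelength `Wmin = 2` px (Nyquist), radial scaling factor
#' `M = 2.2` between successive scales, radial bandwidth ratio
#' `sigma_r = 0.55` (about two octaves), `Nscale = 4` scales, `Nori = 10`
#' candidate orientations with angular scaling factor `T = 1.3`.
#'
#' @param Wmin wavelength of the smallest-scale filter, in pixels (>= 2;
#'   2 px is the shortest representable wavelength).
#' @param M radial scaling factor between successive scales; must exceed 1
#'   when `Nscale > 1`.
#' @param T_ang angular scaling factor controlling the angular bandwidth
#'   via `sigma_theta = T_ang * pi / Nori`.
#' @param sigma_r radial bandwidth ratio, strictly between 0 and 1; smaller
#'   values give wider pass-bands (see [bandwidth_octaves()]).
#' @param Nscale number of radial scales (>= 1).
#' @param Nori number of candidate orientations (>= 1), evenly spaced on
#'   `[0, pi)`.
#' @param image_shape integer vector `c(rows, cols)` of the ROI the filters
#'   will be applied to.
#' @return An object of class `"lg_config"`: a validated list with the
#'   above fields.
#' @seealso [build_bank()], [wavelength_schedule()]
#' @examples
#' cfg <- lg_config()
#' wavelength_schedule(cfg)
#' @export
lg_config <- function(Wmin = 2, M = 2.2, T_ang = 1.3, sigma_r = 0.55,
                      Nscale = 4L, Nori = 10L, image_shape = c(32L, 32L)) {
  for (nm in c("Wmin", "M", "T_ang", "sigma_r"))
    stopifnot_scalar(get(nm), nm)
  Nscale <- as.integer(Nscale); Nori <- as.integer(Nori)
  image_shape <- as.integer(image_shape)
  if (Wmin < 2) stop("'Wmin' must be >= 2 px (Nyquist wavelength)", call. = FALSE)
  if (Nscale < 1L || Nori < 1L) stop("'Nscale' and 'Nori' must be >= 1", call. = FALSE)
  if (M < 1) stop("'M' must be >= 1", call. = FALSE)
  if (sigma_r <= 0 || sigma_r >= 1) stop("'sigma_r' must lie in (0, 1)", call. = FALSE)
  if (T_ang <= 0) stop("'T_ang' must be positive", call. = FALSE)
  if (length(image_shape) != 2L || any(image_shape < 1L))
    stop("'image_shape' must be two positive integers", call. = FALSE)
  structure(list(Wmin = Wmin, M = M, T_ang = T_ang, sigma_r = sigma_r,
                 Nscale = Nscale, Nori = Nori, image_shape = image_shape),
            class = "lg_config")
}

#' @export
print.lg_config <- function(x, ...) {
  cat("Log-Gabor bank configuration\n")
  cat(sprintf("  scales: %d (Wmin = %g px, M = %g)\n", x$Nscale, x$Wmin, x$M))
  cat(sprintf("  orientations: %d (T = %g, sigma_theta = %.4f rad)\n",
              x$Nori, x$T_ang, angular_sigma(x$T_ang, x$Nori)))
  cat(sprintf("  sigma_r = %g (%.2f octaves)\n", x$sigma_r,
              bandwidth_octaves(x$sigma_r)))
  cat(sprintf("  image shape: %d x %d\n", x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Wavelength schedule of the radial scales
#'
#' Scale `S` (1-based) has wavelength `Wmin * M^(S-1)` pixels, a geometric
#' progression from the finest to the coarsest scale.
#'
#' @param config an [lg_config()] object.
#' @return Numeric vector of length `Nscale`, in pixels.
#' @export
wavelength_schedule <- function(config) {
  stopifnot(inherits(config, "lg_config"))
  config$Wmin * config$M^(seq_len(config$Nscale) - 1)
}

#' Center frequency of a filter from its wavelength
#'
#' @param wavelength wavelength in pixels (> 0).
#' @return Center frequency `f0 = 1/wavelength`, in cycles/pixel.
#' @export
center_frequency <- function(wavelength) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("'wavelength' must be positive", call. = FALSE)
  1 / wavelength
}

#' Candidate orientation angles
#'
#' Orientations are evenly spaced over the half-circle:
#' `theta0(i) = i * pi / Nori` for `i = 0, ..., Nori - 1`. With the default
#' `Nori = 10` this is `0, pi/10, ..., 9*pi/10`.
#'
#' @param Nori number of orientations (>= 1).
#' @return Numeric vector of angles in radians, all in `[0, pi)`.
#' @export
orientation_angles <- function(Nori) {
  Nori <- as.integer(Nori)
  if (Nori < 1L) stop("'Nori' must be >= 1", call. = FALSE)
  (seq_len(Nori) - 1) * pi / Nori
}

#' Angular standard deviation of the orientation Gaussian
#'
#' `sigma_theta = T_ang * pi / Nori`: larger `T_ang` widens each filter's
#' angular lobe and increases overlap between neighbouring orientations.
#'
#' @param T_ang angular scaling factor (> 0).
#' @param Nori number of orientations (>= 1).
#' @return Angular standard deviation in radians.
#' @export
angular_sigma <- function(T_ang, Nori) {
  if (T_ang <= 0) stop("'T_ang' must be positive", call. = FALSE)
  Nori <- as.integer(Nori)
  if (Nori < 1L) stop("'Nori' must be >= 1", call. = FALSE)
  T_ang * pi / Nori
}

#' Radial transfer function
#'
#' Gaussian on the log-frequency axis:
#' `exp(-(ln(r/f0))^2 / (2 * (ln sigma_r)^2))`, with the response forced to
#' zero at `r = 0` (the DC singularity of the logarithm). Peaks at 1 when
#' `r = f0`.
#'
#' @param r radial frequency, cycles/pixel (vectorized; >= 0).
#' @param f0 center frequency, cycles/pixel (> 0).
#' @param sigma_r bandwidth ratio in (0, 1).
#' @return Responses in `[0, 1]`, same shape as `r`.
#' @export
radial_transfer <- function(r, f0, sigma_r) {
  if (f0 <= 0) stop("'f0' must be positive", call. = FALSE)
  if (sigma_r <= 0 || sigma_r >= 1) stop("'sigma_r' must lie in (0, 1)", call. = FALSE)
  out <- r
  zero <- r <= 0
  rr <- ifelse(zero, 1, r)        # placeholder; overwritten below
  out[] <- exp(-(log(rr / f0))^2 / (2 * log(sigma_r)^2))
  out[zero] <- 0
  out
}

#' Angular transfer function
#'
#' Gaussian on the wrapped angular difference:
#' `exp(-D^2 / (2 * sigma_theta^2))` with
#' `D = atan2(sin(theta - theta0), cos(theta - theta0))`, so the response is
#' continuous across the `+/-pi` branch cut.
#'
#' @param theta polar angle(s), radians.
#' @param theta0 filter orientation, radians.
#' @param sigma_theta angular standard deviation, radians (> 0).
#' @return Responses in `[0, 1]`, same shape as `theta`.
#' @export
angular_transfer <- function(theta, theta0, sigma_theta) {
  if (sigma_theta <= 0) stop("'sigma_theta' must be positive", call. = FALSE)
  d <- atan2(sin(theta - theta0), cos(theta - theta0))
  exp(-d^2 / (2 * sigma_theta^2))
}

#' Half-amplitude bandwidth of the radial filter, in octaves
#'
#' The two frequencies where [radial_transfer()] drops to one half of its
#' peak are `f0 * sigma_r^(+/- sqrt(2 ln 2))`; their log2 ratio gives the
#' closed form `2 * sqrt(2 ln 2) * |ln sigma_r| / ln 2`. A ratio of 0.75
#' corresponds to roughly one octave, 0.55 to roughly two.
#'
#' @param sigma_r bandwidth ratio in (0, 1).
#' @return Bandwidth in octaves.
#' @export
bandwidth_octaves <- function(sigma_r) {
  if (any(sigma_r <= 0) || any(sigma_r >= 1))
    stop("'sigma_r' must lie in (0, 1)", call. = FALSE)
  2 * sqrt(2 * log(2)) * abs(log(sigma_r)) / log(2)
}

#' Polar frequency grid for an image shape
#'
#' Builds the per-pixel normalized radial frequency and polar angle used to
#' evaluate filter transfer functions. Frequencies are normalized per axis
#' to cycles/pixel in `[-0.5, 0.5)` and laid out in FFT order (DC at index
#' `[1, 1]`), so a transfer array can be multiplied directly with
#' `fft(image)`.
#'
#' @param image_shape integer `c(rows, cols)`.
#' @return List with `radius` (DC entry set to 0), `angle` (radians in
#'   `(-pi, pi]`), both `rows x cols` matrices.
#' @export
frequency_grid <- function(image_shape) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L))
  fy <- fft_freqs(image_shape[1])
  fx <- fft_freqs(image_shape[2])
  FY <- matrix(fy, nrow = image_shape[1], ncol = image_shape[2])
  FX <- matrix(fx, nrow = image_shape[1], ncol = image_shape[2], byrow = TRUE)
  radius <- sqrt(FY^2 + FX^2)
  angle <- atan2(FY, FX)
  radius[1, 1] <- 0
  list(radius = radius, angle = angle)
}

# Normalized FFT sample frequencies for n samples: 0, 1/n, ... wrapped to
# [-0.5, 0.5).
fft_freqs <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

#' Construct a single 2D Log-Gabor filter
#'
#' Multiplies the radial and angular transfer functions on the polar
#' frequency grid of the configured image shape. The DC entry is forced to
#' zero, so the filter passes no constant component. The angular lobe is
#' one-sided (not symmetrized about the origin); spatial responses are
#' therefore complex and downstream code keeps their real part.
#'
#' @param config an [lg_config()].
#' @param scale_index scale `S` in `1..Nscale`.
#' @param theta0 orientation angle, radians.
#' @return An object of class `"lg_filter"`: list with `transfer`
#'   (rows x cols real matrix in `[0, 1]`), `scale`, `wavelength`, `f0`,
#'   `theta0`, `sigma_theta`.
#' @export
build_filter <- function(config, scale_index, theta0) {
  stopifnot(inherits(config, "lg_config"))
  scale_index <- as.integer(scale_index)
  if (scale_index < 1L || scale_index > config$Nscale)
    stop("'scale_index' out of range", call. = FALSE)
  wl <- config$Wmin * config$M^(scale_index - 1)
  f0 <- center_frequency(wl)
  st <- angular_sigma(config$T_ang, config$Nori)
  g <- frequency_grid(config$image_shape)
  transfer <- radial_transfer(g$radius, f0, config$sigma_r) *
    angular_transfer(g$angle, theta0, st)
  transfer[1, 1] <- 0
  structure(list(transfer = transfer, scale = scale_index, wavelength = wl,
                 f0 = f0, theta0 = theta0, sigma_theta = st),
            class = "lg_filter")
}

#' Assemble a bank of Log-Gabor filters
#'
#' Builds `Nscale x Nori` filters (the full candidate bank), or a selected
#' subset when a per-scale list of orientation angles is supplied. Filters
#' are ordered scale-major, then by ascending orientation angle; the
#' construction is fully deterministic.
#'
#' @param config an [lg_config()].
#' @param angles optional list of length `Nscale`; element `S` holds the
#'   orientation angles retained at scale `S` (possibly empty). Defaults to
#'   the full candidate set [orientation_angles()] at every scale.
#' @return An object of class `"lg_bank"`: list with `filters` (list of
#'   [build_filter()] results), `config`, and `index` (data.frame with
#'   columns `scale`, `theta0`, `wavelength`, `f0`).
#' @examples
#' bank <- build_bank(lg_config())
#' length(bank$filters)  # 40
#' @export
build_bank <- function(config, angles = NULL) {
  stopifnot(inherits(config, "lg_config"))
  if (is.null(angles)) {
    angles <- rep(list(orientation_angles(config$Nori)), config$Nscale)
  }
  if (length(angles) != config$Nscale)
    stop("'angles' must list orientations for each scale", call. = FALSE)
  filters <- list()
  idx <- list()
  for (s in seq_len(config$Nscale)) {
    th <- sort(angles[[s]])
    for (t0 in th) {
      f <- build_filter(config, s, t0)
      filters[[length(filters) + 1L]] <- f
      idx[[length(idx) + 1L]] <- data.frame(scale = s, theta0 = t0,
                                            wavelength = f$wavelength, f0 = f$f0)
    }
  }
  index <- if (length(idx)) do.call(rbind, idx)
  else data.frame(scale = integer(), theta0 = numeric(),
                  wavelength = numeric(), f0 = numeric())
  structure(list(filters = filters, config = config, index = index),
            class = "lg_bank")
}

#' @export
print.lg_bank <- function(x, ...) {
  cat(sprintf("Log-Gabor filter bank: %d filters over %d scales (%d x %d grid)\n",
              length(x$filters), x$config$Nscale,
              x$config$image_shape[1], x$config$image_shape[2]))
  tab <- table(factor(x$index$scale, levels = seq_len(x$config$Nscale)))
  cat("  orientations per scale:", paste(as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Montage plot of a filter bank
#'
#' Draws each filter, one row per scale, either as the frequency-domain
#' transfer (FFT-shifted so DC is central) or as the real part of the
#' spatial kernel.
#'
#' @param x an `"lg_bank"`.
#' @param domain `"frequency"` or `"spatial"`.
#' @param ... ignored.
#' @export
plot.lg_bank <- function(x, domain = c("frequency", "spatial"), ...) {
  domain <- match.arg(domain)
  scales <- sort(unique(x$index$scale))
  per_scale <- max(table(x$index$scale))
  op <- graphics::par(mfrow = c(length(scales), per_scale),
                      mar = c(0.2, 0.2, 0.2, 0.2))
  on.exit(graphics::par(op))
  for (s in scales) {
    for (i in which(x$index$scale == s)) {
      m <- x$filters[[i]]$transfer
      if (domain == "frequency") m <- fftshift2(m)
      else m <- Re(ifft2(m + 0i)) |> fftshift2()
      graphics::image(t(m)[, nrow(m):1], axes = FALSE, col = grDevices::gray.colors(64))
    }
  }
  invisible(x)
}

# Move DC to the center of the array for display.
fftshift2 <- function(m) {
  r <- nrow(m); c <- ncol(m)
  m[c((r %/% 2 + 1):r, 1:(r %/% 2)), c((c %/% 2 + 1):c, 1:(c %/% 2))]
}
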
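test_that("wavelength schedule follows the geometric progression", {
  cfg <- lg_config(Wmin = 2, M = 2.2, Nscale = 4)
  expect_equal(wavelength_schedule(cfg), c(2, 4.4, 9.68, 21.296))
  expect_equal(wavelength_schedule(lg_config(Wmin = 2, M = 2.2, Nscale = 1)), 2)
  # degenerate M = 1: constant schedule
  expect_equal(wavelength_schedule(lg_config(Wmin = 3, M = 1, Nscale = 3)),
               c(3, 3, 3))
  expect_true(all(diff(wavelength_schedule(cfg)) > 0))
})

test_that("center frequency is the reciprocal wavelength", {
  expect_equal(center_frequency(2), 0.5)
  expect_equal(center_frequency(4.4), 1 / 4.4)
  expect_error(center_frequency(0), "positive")
  expect_error(center_frequency(-3), "positive")
})

test_that("orientation angles are evenly spaced over the half-circle", {
  expect_equal(orientation_angles(10), (0:9) * pi / 10)
  expect_equal(orientation_angles(1), 0)
  expect_equal(orientation_angles(4), c(0, pi / 4, pi / 2, 3 * pi / 4))
  a <- orientation_angles(7)
  expect_true(all(a >= 0 & a < pi))
})

test_that("angular sigma scales as T * pi / Nori", {
  expect_equal(angular_sigma(1.0, 10), pi / 10)
  expect_equal(angular_sigma(1.3, 10), 1.3 * pi / 10)
  expect_equal(angular_sigma(1.3, 1), 1.3 * pi)
})

test_that("radial transfer peaks at f0 and vanishes at DC", {
  expect_equal(radial_transfer(0.25, 0.25, 0.55), 1)
  expect_equal(radial_transfer(0, 0.25, 0.55), 0)
  r <- seq(0, 0.5, length.out = 200)
  v <- radial_transfer(r, 0.1, 0.55)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(r[which.max(v)], 0.1, tolerance = 0.01)
})

test_that("angular transfer is a wrapped Gaussian, continuous across +/- pi", {
  st <- angular_sigma(1.3, 10)
  expect_equal(angular_transfer(0.4, 0.4, st), 1)
  expect_equal(angular_transfer(0.4 + st, 0.4, st), exp(-1 / 2))
  # wrap-around: theta0 = 9pi/10 is only pi/10 + eps away from -pi + eps
  eps <- 1e-3
  d_expected <- atan2(sin(-pi + eps - 9 * pi / 10), cos(-pi + eps - 9 * pi / 10))
  expect_equal(angular_transfer(-pi + eps, 9 * pi / 10, st),
               exp(-d_expected^2 / (2 * st^2)))
  # continuity across the branch cut
  lo <- angular_transfer(pi - eps, 9 * pi / 10, st)
  hi <- angular_transfer(-pi + eps, 9 * pi / 10, st)
  expect_equal(lo, hi, tolerance = 0.05)
})

test_that("half-amplitude bandwidth matches both the closed form and root finding", {
  for (sr in c(0.3, 0.55, 0.75, 0.9)) {
    closed <- bandwidth_octaves(sr)
    f0 <- 0.1
    g <- function(r) radial_transfer(r, f0, sr) - 0.5
    f_lo <- uniroot(g, c(1e-9, f0), tol = 1e-12)$root
    f_hi <- uniroot(g, c(f0, 10), tol = 1e-12)$root
    expect_equal(log2(f_hi / f_lo), closed, tolerance = 1e-6)
  }
  # monotone decreasing, vanishing as sigma_r -> 1
  expect_true(all(diff(bandwidth_octaves(c(0.5, 0.6, 0.7, 0.8, 0.99))) < 0))
  expect_lt(bandwidth_octaves(0.999), 0.01)
})

test_that("single filters are products of their polar components", {
  cfg <- tiny_config()
  th0 <- pi / 3
  f <- build_filter(cfg, 1, th0)
  expect_true(all(f$transfer >= 0 & f$transfer <= 1))
  expect_equal(f$transfer[1, 1], 0)
  g <- frequency_grid(cfg$image_shape)
  expected <- radial_transfer(g$radius, f$f0, cfg$sigma_r) *
    angular_transfer(g$angle, th0, f$sigma_theta)
  expected[1, 1] <- 0
  expect_equal(f$transfer, expected)
})

test_that("the peak of each filter sits at its nominal frequency and angle", {
  cfg <- lg_config(image_shape = c(32L, 32L))
  g <- frequency_grid(cfg$image_shape)
  step <- 1 / 32
  for (s in c(1, 3)) for (th in c(0, 2 * pi / 5)) {
    f <- build_filter(cfg, s, th)
    peak <- which(f$transfer == max(f$transfer), arr.ind = TRUE)[1, ]
    pr <- g$radius[peak[1], peak[2]]
    pa <- g$angle[peak[1], peak[2]]
    expect_lt(abs(pr - f$f0), 1.5 * step)
    # angular grid step near radius pr is about step / pr
    expect_lt(abs(atan2(sin(pa - th), cos(pa - th))), 1.5 * step / pr)
  }
})

test_that("the candidate bank has Nscale x Nori deterministic filters, ordered by scale", {
  cfg <- lg_config()
  bank <- build_bank(cfg)
  expect_length(bank$filters, 40L)
  expect_equal(bank$index$scale, rep(1:4, each = 10))
  expect_length(build_bank(lg_config(Nscale = 1, Nori = 1))$filters, 1L)
  bank2 <- build_bank(cfg)
  expect_identical(lapply(bank$filters, `[[`, "transfer"),
                   lapply(bank2$filters, `[[`, "transfer"))
  # normalization over the whole bank
  for (f in bank$filters) {
    expect_true(all(f$transfer >= 0 & f$transfer <= 1))
    expect_identical(f$transfer[1, 1], 0)
  }
  # scale ordering: coarser scales peak at lower radius
  g <- frequency_grid(cfg$image_shape)
  peak_radius <- vapply(bank$filters, function(f) {
    p <- which(f$transfer == max(f$transfer), arr.ind = TRUE)[1, ]
    g$radius[p[1], p[2]]
  }, numeric(1))
  by_scale <- tapply(peak_radius, bank$index$scale, mean)
  expect_true(all(diff(by_scale) < 0))
})

test_that("configuration invariants are validated", {
  expect_error(lg_config(Wmin = 1.5), "Wmin")
  expect_error(lg_config(sigma_r = 1.2), "sigma_r")
  expect_error(lg_config(sigma_r = 0), "sigma_r")
  expect_error(lg_config(T_ang = -1), "T_ang")
  expect_error(lg_config(Nscale = 0), "Nscale")
  expect_error(lg_config(M = 0.5), "M")
})
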
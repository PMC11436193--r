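test_that("Log-Gabor convolution is linear, DC-free, and matches the spatial oracle", {
  cfg <- tiny_config()
  f <- build_filter(cfg, 2, pi / 4)
  expect_equal(loggabor_conv(matrix(0.7, 8, 8), f), matrix(0, 8, 8),
               tolerance = 1e-12)
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  expect_equal(loggabor_conv(3.5 * img, f), 3.5 * loggabor_conv(img, f))
  expect_lt(max(abs(loggabor_conv(img, f) - spatial_conv_oracle(img, f$transfer))),
            1e-8)
  expect_error(loggabor_conv(matrix(0, 4, 4), f), "shape")
})

test_that("layer outputs have the contracted counts and parent grouping", {
  cfg <- tiny_config(shape = c(8L, 8L))
  imgs <- random_images(3, c(8, 8))
  m <- vfdcn(imgs, cfg, per_scale_counts = c(1, 2), block_shape = c(4, 4))
  expect_equal(m$K1, 3L)
  expect_equal(m$K2, 3L)
  l1 <- layer1(imgs[[1]], m)
  expect_length(l1, 3L)
  l2 <- layer2(l1, m)
  expect_length(l2, 3L)
  expect_true(all(lengths(l2) == 3L))
  # layer-2 output for parent j depends only on layer-1 map j
  l1b <- l1
  l1b[[2]] <- l1b[[2]] + 1
  l2b <- layer2(l1b, m)
  expect_identical(l2b[[1]], l2[[1]])
  expect_identical(l2b[[3]], l2[[3]])
  expect_false(identical(l2b[[2]], l2[[2]]))
})

test_that("binary hashing weights the Heaviside bits by powers of two", {
  pos <- matrix(1, 2, 2); neg <- matrix(-1, 2, 2); zer <- matrix(0, 2, 2)
  expect_equal(binary_hash(list(pos, pos, pos)), matrix(7, 2, 2))
  expect_equal(binary_hash(list(neg, zer, neg)), matrix(0, 2, 2))
  expect_equal(binary_hash(list(pos, neg, pos)), matrix(5, 2, 2))
  expect_error(binary_hash(list(pos, matrix(1, 3, 3))), "shape")
})

test_that("contrast inversion complements the code at pixels with no zero response", {
  cfg <- tiny_config()
  f <- lapply(c(0, pi / 4, pi / 2), function(t) build_filter(cfg, 2, t))
  set.seed(3)
  img <- matrix(runif(64), 8, 8)
  maps <- lapply(f, loggabor_conv, image = img)
  maps_neg <- lapply(f, loggabor_conv, image = -img)
  ok <- Reduce(`&`, lapply(maps, function(m) m != 0))
  t_pos <- binary_hash(maps); t_neg <- binary_hash(maps_neg)
  expect_equal(t_neg[ok], (2^3 - 1) - t_pos[ok])
})

test_that("block histograms conserve pixel counts and match hand tallies", {
  # uniform map: point mass at its value in every block
  h <- blockwise_histogram(matrix(3, 4, 4), c(2, 2), K2 = 2)
  expect_equal(h$length, 4 * 4)        # 2^2 bins x 4 blocks
  expect_equal(h$index, c(4, 8, 12, 16))  # bin 3 (0-based) in each block
  expect_equal(h$count, rep(4L, 4))
  # hand-worked 4x4 with values 0..3, 2x2 blocks (row-major block order)
  enc <- matrix(c(0, 1, 2, 2,
                  1, 1, 3, 2,
                  0, 0, 0, 1,
                  0, 0, 1, 3), 4, 4, byrow = TRUE)
  h <- blockwise_histogram(enc, c(2, 2), K2 = 2)
  # block 1 (top-left): {0,1,1,1}; block 2: {2,2,3,2}; block 3: {0,0,0,0};
  # block 4: {0,1,1,3}
  expect_equal(h$index, c(1, 2, 4 + 3, 4 + 4, 8 + 1, 12 + 1, 12 + 2, 12 + 4))
  expect_equal(h$count, c(1L, 3L, 3L, 1L, 4L, 1L, 2L, 1L))
  expect_equal(sum(h$count), 16L)
  expect_error(blockwise_histogram(matrix(0, 5, 4), c(2, 2), 2), "divide")
})

test_that("feature extraction is deterministic with conserved mass and stated length", {
  cfg <- tiny_config(shape = c(16L, 16L))
  imgs <- random_images(4, c(16, 16), seed = 8)
  m <- vfdcn(imgs, cfg, per_scale_counts = c(2, 2), block_shape = c(8, 8))
  f1 <- extract_feature(imgs[[1]], m)
  expect_equal(f1$length, 2^m$K2 * m$K1 * m$B)
  expect_equal(sum(f1$count), m$K1 * 16 * 16)
  expect_true(all(f1$count > 0))
  expect_identical(extract_feature(imgs[[1]], m), f1)
  expect_error(extract_feature(matrix(0, 8, 8), m), "shape")
})

test_that("mass conservation and code range hold across random models and images", {
  set.seed(21)
  for (trial in 1:10) {
    n <- sample(c(8L, 16L), 1)
    cfg <- lg_config(Nscale = sample(1:2, 1), Nori = sample(2:4, 1),
                     image_shape = c(n, n))
    counts <- pmin(sample(1:2, cfg$Nscale, replace = TRUE), cfg$Nori)
    imgs <- random_images(2, c(n, n), seed = 100 + trial)
    bs <- if (n == 8L) c(4L, 4L) else c(8L, 8L)
    m <- vfdcn(imgs, cfg, per_scale_counts = counts, block_shape = bs)
    img <- matrix(runif(n * n), n, n)
    l1 <- layer1(img, m)
    for (grp in layer2(l1, m)) {
      code <- binary_hash(grp)
      expect_true(all(code >= 0 & code <= 2^m$K2 - 1))
      expect_true(all(code == floor(code)))
    }
    f <- extract_feature(img, m)
    expect_equal(sum(f$count), m$K1 * n * n)
    expect_true(all(f$index >= 1 & f$index <= f$length))
  }
})

test_that("fitting with the default diamond keeps 18 filters per layer", {
  spec <- synth_spec(n_classes = 3, samples_per_class = 2)
  ds <- synth_images(spec)
  m <- vfdcn(ds$images)
  expect_equal(m$K1, 18L)
  expect_equal(m$K2, 18L)
  expect_equal(m$B, 16L)
  expect_equal(m$feature_length, 2^18 * 18 * 16)
  m2 <- vfdcn(ds$images)
  expect_identical(m$diamond$angles, m2$diamond$angles)
  expect_identical(m$diamond$weights, m2$diamond$weights)
})

test_that("layer-2 re-selection runs and yields a valid model", {
  cfg <- tiny_config(shape = c(8L, 8L))
  imgs <- random_images(2, c(8, 8), seed = 31)
  m <- vfdcn(imgs, cfg, per_scale_counts = c(1, 2), block_shape = c(4, 4),
             relearn_layer2 = TRUE)
  expect_equal(m$K1, 3L)
  expect_equal(m$K2, 3L)
  f <- extract_feature(imgs[[1]], m)
  expect_equal(sum(f$count), m$K1 * 64)
})
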
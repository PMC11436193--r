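test_that("sparse Euclidean distance has metric basics and the 3-4-5 value", {
  f <- sparse_feat(c(1, 5), c(3, 2), 10)
  g <- sparse_feat(c(2, 5), c(4, 2), 10)
  expect_equal(match_distance(f, f), 0)
  expect_equal(match_distance(f, g), match_distance(g, f))
  a <- sparse_feat(1, 3, 10); b <- sparse_feat(2, 4, 10)
  expect_equal(match_distance(a, b), 5)
  expect_error(match_distance(a, sparse_feat(1, 1, 99)), "dimension")
})

test_that("rank-1 classification picks the nearest label with lowest-index ties", {
  g1 <- sparse_feat(1, 1, 10); g2 <- sparse_feat(2, 1, 10)
  gallery <- list(g1, g2)
  expect_equal(rank1_classify(gallery, c("a", "b"), g2), "b")
  # probe equidistant from both gallery points
  probe <- sparse_feat(3, 1, 10)
  expect_equal(rank1_classify(gallery, c("a", "b"), probe), "a")
  expect_error(rank1_classify(list(), character(0), probe), "empty")
})

test_that("FAR/FRR endpoints, hand counts and monotonicity are correct", {
  g <- c(1, 2); i <- c(3, 4)
  sw <- far_frr(g, i, thresholds = c(0.5, 2.5, 10))
  expect_equal(sw$FAR, c(0, 0, 100))
  expect_equal(sw$FRR, c(100, 0, 0))
  set.seed(9)
  sw <- far_frr(rnorm(200, 1), rnorm(300, 2))
  expect_true(all(diff(sw$FAR) >= 0))
  expect_true(all(diff(sw$FRR) <= 0))
  expect_error(far_frr(numeric(0), i), "nonempty")
})

test_that("EER hits the analytic values for simple score constructions", {
  # fully separated
  expect_equal(compute_eer(c(1, 2, 3), c(5, 6, 7)), 0)
  # identical distributions -> ~50%
  set.seed(10)
  x <- runif(20000); y <- runif(20000)
  expect_equal(compute_eer(x, y), 50, tolerance = 0.04)
  # genuine U(0,1) vs imposter U(0.5,1.5): crossing at t = 0.75, EER 25%
  g <- runif(20000); i <- runif(20000, 0.5, 1.5)
  expect_equal(compute_eer(g, i), 25, tolerance = 0.06)
})

test_that("open-set splits partition identities deterministically", {
  labels <- rep(sprintf("c%02d", 1:10), each = 3)
  sp <- open_set_split(labels, 0.5, seed = 7)
  expect_length(sp$train_classes, 5L)
  expect_length(sp$test_classes, 5L)
  expect_length(intersect(sp$train_classes, sp$test_classes), 0L)
  expect_setequal(c(sp$train_classes, sp$test_classes), unique(labels))
  expect_identical(open_set_split(labels, 0.5, seed = 7), sp)
  expect_false(identical(open_set_split(labels, 0.5, seed = 8)$train_classes,
                         sp$train_classes))
  expect_error(open_set_split(rep("a", 5)), "two classes")
})

test_that("evaluation is reproducible and collapses to chance under label shuffling", {
  cfg <- tiny_config(shape = c(16L, 16L))
  spec <- synth_spec(n_classes = 6, samples_per_class = 4,
                     image_shape = c(16, 16), stroke_width = c(1.5, 4))
  ds <- synth_images(spec)
  r1 <- evaluate_recognition(ds$images, ds$labels, cfg,
                             per_scale_counts = c(2, 3), block_shape = c(8, 8),
                             n_iterations = 1, seed = 3)
  r2 <- evaluate_recognition(ds$images, ds$labels, cfg,
                             per_scale_counts = c(2, 3), block_shape = c(8, 8),
                             n_iterations = 1, seed = 3)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$roc, r2$roc)
  expect_true(r1$EER >= 0 && r1$EER <= 100)
  # shuffled labels destroy identity structure: ACC near chance, EER near 50
  set.seed(44); sh <- sample(ds$labels)
  r3 <- evaluate_recognition(ds$images, sh, cfg,
                             per_scale_counts = c(2, 3), block_shape = c(8, 8),
                             n_iterations = 1, seed = 3)
  expect_lt(r3$ACC, 75)
  expect_gt(r3$EER, 20)
})

test_that("single-parameter sweeps mirror lone evaluations and reject bad grids", {
  cfg <- tiny_config(shape = c(16L, 16L))
  spec <- synth_spec(n_classes = 6, samples_per_class = 3,
                     image_shape = c(16, 16))
  ds <- synth_images(spec)
  base <- evaluate_recognition(ds$images, ds$labels, cfg,
                               per_scale_counts = c(2, 3),
                               block_shape = c(8, 8), n_iterations = 1, seed = 2)
  sw <- run_sweep(ds$images, ds$labels, "T", c(1.3),
                  config = cfg, per_scale_counts = c(2, 3),
                  block_shape = c(8, 8), n_iterations = 1, seed = 2)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$EER, base$EER)
  expect_equal(sw$ACC, base$ACC)
  swd <- run_sweep(ds$images, ds$labels, "diamond",
                   list(c(4, 0), c(0, 4), c(2, 3)),
                   config = cfg, block_shape = c(8, 8),
                   n_iterations = 1, seed = 2)
  expect_equal(nrow(swd), 3L)
  expect_equal(swd$value, c("[4,0]", "[0,4]", "[2,3]"))
  expect_error(run_sweep(ds$images, ds$labels, "sigma_r", c(0.5), config = cfg))
})
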
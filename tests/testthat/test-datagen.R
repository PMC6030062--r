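test_that("rectangle prototypes are normalized box indicators", {
  p <- make_rectangle_classes(5, 2, lambda = 100, alpha = 10)
  expect_equal(sum(p$W[1, ] > 1e-6), 4)
  expect_equal(max(p$W[1, ]), 0.25)
  expect_equal(rowSums(p$W), 1, ignore_attr = TRUE)
  p3 <- make_rectangle_classes(8, c(2, 3, 4), lambda = c(50, 150, 300))
  expect_equal(rowSums(p3$W), rep(1, 3), tolerance = 1e-12)
  expect_error(make_rectangle_classes(4, c(2, 5), lambda = c(1, 2)), "fit")
})

test_that("EM recovers the box supports from sampled rectangle images", {
  p <- rectangle_fixture()
  d <- sample_gp_dataset(p, 2000, seed = 81)
  pick <- vapply(1:3, function(c) which(d$true_c == c)[1], integer(1))
  init <- gp_params(d$Y[pick, ] / rowSums(d$Y[pick, ]), alpha = rep(2, 3),
                    beta = 2 / pmax(d$brightness[pick], 1))
  out <- run_em(d, init, iters = 40)
  perm <- match_classes(out$params$W, p$W)
  W <- out$params$W[perm, ]
  for (c in 1:3) {
    on_box <- p$W[c, ] > 1e-6  # feature rows are floored, not exactly zero
    expect_true(all(W[c, on_box] > 0.01))
    expect_true(all(W[c, !on_box] < 0.01))
  }
})

test_that("shape normalization hits the target mass with unit background", {
  expect_equal(normalize_shape_only(rep(1, 4), A = 8), rep(2, 4))
  set.seed(12)
  raw <- matrix(runif(400) * rbinom(400, 1, 0.3), 1, 400)
  out <- normalize_shape_only(raw, A = 500)
  expect_equal(sum(out), 500, tolerance = 1e-9)
  expect_true(all(out >= 1))
  # scale invariance
  expect_equal(normalize_shape_only(3.7 * raw[1, ], A = 500),
               normalize_shape_only(raw[1, ], A = 500), tolerance = 1e-12)
  expect_error(normalize_shape_only(rep(0, 4), A = 8), "positive")
  expect_error(normalize_shape_only(rep(1, 4), A = 3), "exceed")
  # property over random batches
  for (i in 1:5) {
    raw_b <- matrix(rgamma(5 * 50, 1), 5, 50)
    out_b <- normalize_shape_only(raw_b, A = 80)
    expect_equal(rowSums(out_b), rep(80, 5), tolerance = 1e-9)
    expect_true(all(out_b >= 1))
  }
})

test_that("brightness-preserving transform keeps relative brightness and unit background", {
  raw <- rbind(c(rep(10, 10), rep(0, 10)), c(rep(30, 10), rep(0, 10)))
  out <- brighten_preserving(raw, A = 40)
  # f = (100, 300) / 200 = (0.5, 1.5)
  D <- 20
  expect_equal(rowSums(out) - D, (40 - D) * c(0.5, 1.5), tolerance = 1e-9)
  expect_true(all(out >= 1))
  # brightness rank order is conserved
  set.seed(13)
  raw2 <- matrix(rgamma(8 * 30, 1), 8, 30)
  out2 <- brighten_preserving(raw2, A = 60)
  expect_equal(order(rowSums(out2)), order(rowSums(raw2)))
})

test_that("class-dependent brightening follows the pinned transform", {
  # single image: f = 1; all pixels equal so y_SA = 3 with A = 12, D = 4
  raw <- matrix(5, 1, 4)
  out <- brighten_class_dependent(raw, labels = 1, A = 12)
  expect_equal(out[1, ], rep((3 - 1) * (1 + 2.3) + 1, 4))

  # background pixels stay at exactly 1
  raw2 <- matrix(c(4, 4, 0, 0), 1, 4)
  out2 <- brighten_class_dependent(raw2, labels = 5, A = 12)
  expect_equal(out2[1, 3:4], c(1, 1))

  # balanced batch mean brightness: (A - D)(1 + mean(v)) + D
  set.seed(14)
  n <- 1000
  labels <- rep(1:10, each = n / 10)
  raw3 <- matrix(rgamma(n * 100, 4), n, 100)
  out3 <- brighten_class_dependent(raw3, labels, A = 200)
  v <- brightening_offsets()
  expected <- (200 - 100) * (1 + mean(v)) + 100
  expect_equal(mean(rowSums(out3)), expected, tolerance = 0.02)
  expect_error(brighten_class_dependent(raw3, rep(11, n), A = 200), "range")
})

test_that("spectrogram trimming keeps a fixed window and applies both discard rules", {
  mk <- function(Tn, hot, value = 100) {
    sp <- matrix(0, 8, Tn)
    sp[, hot] <- value
    sp
  }
  # all energy at one interior column
  out <- trim_spectrogram(mk(400, 200), half_width = 50)
  expect_true(out$kept)
  expect_equal(ncol(out$spec), 101)
  expect_equal(out$energy_fraction, 1.0)
  expect_equal(out$com, 200)

  # energy too close to the start
  out2 <- trim_spectrogram(mk(400, 31), half_width = 50)
  expect_false(out2$kept)
  expect_equal(out2$reason, "edge")

  # uniform energy: retains only 101/400 < 0.65
  out3 <- trim_spectrogram(matrix(1, 8, 400), half_width = 50)
  expect_false(out3$kept)
  expect_equal(out3$reason, "energy")
  expect_equal(out3$energy_fraction, 101 / 400, tolerance = 1e-12)

  # short recordings fall back to all columns, with a message
  expect_message(trim_spectrogram(matrix(1, 8, 10), n_top_bins = 20,
                                  half_width = 2), "shorter")
})

test_that("synthetic logatomes have class-typical brightness and are reproducible", {
  gen <- make_logatome_params(seed = 2)
  d <- make_synthetic_logatomes(500, params = gen, seed = 2)
  for (c in 1:4) {
    m <- mean(d$brightness[d$labels == c])
    expect_lt(abs(m - gen$lambda[c]) / gen$lambda[c], 0.02)
  }
  d2 <- make_synthetic_logatomes(10, params = gen, seed = 5)
  d3 <- make_synthetic_logatomes(10, params = gen, seed = 5)
  expect_identical(d2$Y, d3$Y)

  # vanishing intensity variance and no observation noise: near-identical
  # samples within a class
  gen_det <- make_logatome_params(beta = 1e6, seed = 2)
  dd <- make_synthetic_logatomes(5, params = gen_det, seed = 3,
                                 poisson = FALSE)
  for (c in 1:4) {
    block <- dd$Y[dd$labels == c, ]
    expect_lte(max(abs(sweep(block, 2L, block[1, ]))), 1)
  }
})

test_that("sentences balance classes and respect the seed", {
  gen <- make_logatome_params(seed = 4)
  test_set <- make_synthetic_logatomes(20, params = gen, seed = 4)
  s10 <- build_sentence(test_set, 10, seed = 1)
  counts <- table(factor(s10$labels, levels = 1:4))
  expect_true(all(counts >= 2))
  expect_equal(sum(counts), 10)
  s10b <- build_sentence(test_set, 10, seed = 1)
  expect_identical(s10$Y, s10b$Y)
  # pigeonhole: 8 utterances over 4 classes
  s8 <- build_sentence(test_set, 8, seed = 2)
  expect_equal(as.vector(table(factor(s8$labels, levels = 1:4))), rep(2L, 4))
  expect_error(build_sentence(test_set, 6, seed = 1), "two examples")
  tiny <- subset_dataset(test_set, which(test_set$labels == 1)[1:2])
  expect_error(build_sentence(tiny, 10, seed = 1), "not enough")
})

test_that("digit image generator is reproducible and supports shared prototypes", {
  a <- synth_digit_images(40, seed = 3)
  b <- synth_digit_images(40, seed = 3)
  expect_identical(a$images, b$images)
  c <- synth_digit_images(20, prototypes = a$prototypes, seed = 4)
  expect_equal(dim(c$images), c(20, 400))
  expect_equal(c$prototypes, a$prototypes)
  # balanced labels
  expect_equal(as.vector(table(a$labels)), rep(4L, 10))
})
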
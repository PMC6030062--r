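test_that("nb_log_pmf matches closed forms, normalizes, and agrees with stats::dnbinom", {
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  # truncated normalization
  expect_equal(sum(exp(nb_log_pmf(0:500, 2, 3))), 1, tolerance = 1e-10)
  # independent route through base R's NB parameterization
  k <- 0:40
  expect_equal(nb_log_pmf(k, 2.5, 0.7),
               dnbinom(k, size = 2.5, prob = 0.7 / 1.7, log = TRUE),
               tolerance = 1e-12)
  expect_error(nb_log_pmf(-1, 1, 1), "non-negative")
  expect_error(nb_log_pmf(1, -1, 1), "positive")
})

test_that("nb_log_pmf matches the Gamma-then-Poisson sampling frequency", {
  set.seed(7)
  n <- 2e5
  z <- rgamma(n, shape = 2, rate = 0.5)
  k <- rpois(n, z)
  p_hat <- mean(k == 3)
  p <- exp(nb_log_pmf(3, 2, 0.5))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(p_hat - p), 4 * se)
})

test_that("sampling respects the feature support and NB brightness moments", {
  p0 <- gp_params(matrix(c(1, 0), 1, 2), alpha = 3, beta = 1)
  d0 <- sample_gp_dataset(p0, 100, seed = 1)
  expect_true(all(d0$Y[, 2] == 0))

  p <- gp_params(matrix(c(0.6, 0.4), 1, 2), alpha = 4, beta = 2)
  d <- sample_gp_dataset(p, 1e4, seed = 2)
  # NB(yhat): mean alpha/beta = 2, variance alpha(beta+1)/beta^2 = 3
  se_mean <- sqrt(3 / 1e4)
  expect_lt(abs(mean(d$brightness) - 2), 3 * se_mean)
  expect_lt(abs(var(d$brightness) - 3), 0.2)
  # reproducibility
  d2 <- sample_gp_dataset(p, 10, seed = 99)
  d3 <- sample_gp_dataset(p, 10, seed = 99)
  expect_identical(d2$Y, d3$Y)

  expect_error(sample_gp_dataset(p, 0), "positive integer")
  expect_error(gp_params(matrix(1, 2, 2), alpha = 1, beta = 1,
                         prior = c(0, 0)), "prior")
})

test_that("joint posterior has the conjugate closed form", {
  p <- gp_params(matrix(c(0.3, 0.7), 1, 2), alpha = 2.5, beta = 1.5)
  y <- c(3, 1)
  post <- joint_posterior(y, p)
  expect_equal(post$s, 1)
  expect_equal(post$z_shape, 2.5 + 4)
  expect_equal(post$z_rate, 2.5)
  expect_equal(post$z_mean, 6.5 / 2.5)

  # symmetry: identical classes share the posterior equally
  p2 <- gp_params(rbind(c(0.3, 0.7), c(0.3, 0.7)), alpha = 2, beta = 1)
  expect_equal(class_posterior(c(5, 2), p2), c(0.5, 0.5), tolerance = 1e-12)

  expect_error(joint_posterior(c(1, 2, 3), p), "dimensions")
})

test_that("closed-form class and intensity posteriors match the quadrature oracle", {
  for (seed in 1:12) {
    inst <- random_small_instance(seed)
    p <- gp_params(inst$W, inst$alpha, inst$beta, inst$prior)
    post <- joint_posterior(inst$y, p)
    oracle <- quad_posterior(inst$y, p$W, p$alpha, p$beta, p$prior)
    expect_equal(post$s, oracle$s, tolerance = 1e-6)
    expect_equal(post$z_mean, oracle$z_mean, tolerance = 1e-6)
    # Eq-1 intensity posterior: mixture of shifted Gammas matches the grid
    z_probe <- quantile(oracle$z_grid, c(0.2, 0.5, 0.8))
    dens_cf <- vapply(z_probe, function(z) {
      sum(post$s * dgamma(z, post$z_shape, rate = post$z_rate))
    }, numeric(1))
    dens_or <- approx(oracle$z_grid, oracle$z_density, xout = z_probe)$y
    expect_equal(dens_cf, dens_or, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("class posterior reduces to NB terms for identical shapes and to shape terms for identical intensities", {
  # identical W rows: only the NB terms decide
  W <- rbind(c(0.4, 0.6), c(0.4, 0.6))
  p <- gp_params(W, alpha = c(2, 6), beta = c(1, 0.5))
  y <- c(4, 3)
  s <- class_posterior(y, p)
  lw <- dnbinom(7, size = c(2, 6), prob = c(1 / 2, 0.5 / 1.5), log = TRUE)
  expect_equal(s, exp(lw) / sum(exp(lw)), tolerance = 1e-12)

  # identical (alpha, beta): NB terms cancel; hand-computed softmax
  p2 <- gp_params(rbind(c(0.9, 0.1), c(0.1, 0.9)), alpha = 2, beta = 1)
  s2 <- class_posterior(c(3, 0), p2)
  expect_equal(s2, c(0.729, 0.001) / 0.730, tolerance = 1e-9)
  expect_equal(sum(s2), 1, tolerance = 1e-12)
})

test_that("posterior mean intensity interpolates the conjugate class means", {
  p <- gp_params(matrix(c(0.5, 0.5), 1, 2), alpha = 2, beta = 1)
  expect_equal(posterior_mean_intensity(c(2, 2), p), 3.0)
  # one-hot posterior via extreme shapes
  p2 <- gp_params(rbind(c(1, 0), c(0, 1)), alpha = c(2, 5), beta = c(1, 2))
  y <- c(6, 0)
  s <- class_posterior(y, p2)
  expect_gt(s[1], 1 - 1e-10)
  expect_equal(posterior_mean_intensity(y, p2), (2 + 6) / 2, tolerance = 1e-8)
})

test_that("log marginal likelihood collapses to the NB pmf and is label-symmetric", {
  p <- gp_params(matrix(1, 1, 1), alpha = 3, beta = 0.8)
  d <- gp_dataset(matrix(5, 1, 1))
  expect_equal(log_marginal_likelihood(d, p), nb_log_pmf(5, 3, 0.8),
               tolerance = 1e-12)

  set.seed(3)
  W <- matrix(rgamma(6, 1), 2, 3); W <- W / rowSums(W)
  p2 <- gp_params(W, alpha = c(2, 4), beta = c(1, 0.5), prior = c(0.3, 0.7))
  d2 <- sample_gp_dataset(p2, 50, seed = 4)
  p2_perm <- gp_params(W[2:1, ], alpha = c(4, 2), beta = c(0.5, 1),
                       prior = c(0.7, 0.3))
  expect_equal(log_marginal_likelihood(d2, p2),
               log_marginal_likelihood(d2, p2_perm), tolerance = 1e-10)
})

test_that("inference stays finite for very bright stimuli", {
  p <- gp_params(rbind(c(0.8, 0.2), c(0.3, 0.7)), alpha = c(2, 3),
                 beta = c(0.01, 0.02))
  y <- c(7e5, 3e5)  # yhat = 1e6
  post <- joint_posterior(y, p)
  expect_true(all(is.finite(post$s)))
  expect_true(is.finite(post$z_mean))
  expect_true(is.finite(log_marginal_likelihood(gp_dataset(rbind(y)), p)))
})

test_that("average posterior mass on the true class beats any label permutation", {
  p <- rectangle_fixture()
  d <- sample_gp_dataset(p, 5000, seed = 11)
  S <- class_responsibilities(d$Y, p)
  score <- function(perm) mean(S[cbind(seq_len(nrow(S)), perm[d$true_c])])
  true_score <- score(1:3)
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pr in perms) expect_gt(true_score, score(pr))
})
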
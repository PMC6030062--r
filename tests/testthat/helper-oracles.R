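# Independent oracles and fixture builders shared across tests.
# The quadrature oracle evaluates the unnormalized joint P(y|c,z) P(z|c) P(c)
# on a fine z grid with base-R densities only; it never calls the package's
# closed-form inference path.

# Brute-force posterior over class and intensity by Simpson-rule quadrature
# on a fine z grid (the integrand is smooth for Gamma shapes >= 1). Returns
# the class posterior, the posterior mean of z, and the z posterior density
# on the grid.
quad_posterior <- function(y, W, alpha, beta, prior = NULL, n_grid = 2^16 + 1) {
  C <- nrow(W)
  if (is.null(prior)) prior <- rep(1 / C, C)
  yhat <- sum(y)
  # generous upper bound across per-class conjugate posteriors
  z_hi <- max(qgamma(1 - 1e-14, shape = alpha + yhat, rate = beta + 1)) * 2
  zg <- seq(0, z_hi, length.out = n_grid)
  h <- zg[2] - zg[1]
  simp <- rep(c(2, 4), length.out = n_grid)  # 4 at even, 2 at odd interior
  simp[c(1, n_grid)] <- 1
  simp <- simp * h / 3
  lik <- matrix(0, n_grid, C)
  for (c in seq_len(C)) {
    loglik <- rowSums(dpois(matrix(y, n_grid, length(y), byrow = TRUE),
                            outer(zg, W[c, ]), log = TRUE))
    lik[, c] <- exp(loglik + dgamma(zg, alpha[c], rate = beta[c], log = TRUE) +
                      log(prior[c]))
  }
  mass <- colSums(lik * simp)
  s <- mass / sum(mass)
  z_mean <- sum(colSums(lik * simp * zg)) / sum(mass)
  dens <- rowSums(lik) / sum(mass)
  list(s = s, z_mean = z_mean, z_grid = zg, z_density = dens)
}

# Random small model instance with a stimulus drawn from it.
random_small_instance <- function(seed, C_max = 4, D_max = 10) {
  set.seed(seed)
  C <- sample(1:C_max, 1)
  D <- sample(2:D_max, 1)
  W <- matrix(rgamma(C * D, 1, 1) + 1e-3, C, D)
  W <- W / rowSums(W)
  alpha <- runif(C, 1, 8)  # shapes >= 1 keep the grid integrand bounded
  beta <- runif(C, 0.2, 2)
  prior <- rgamma(C, 2, 1); prior <- prior / sum(prior)
  c_true <- sample.int(C, 1)
  z <- rgamma(1, alpha[c_true], rate = beta[c_true])
  y <- rpois(D, z * W[c_true, ])
  if (sum(y) > 50) y <- pmin(y, 5)  # keep yhat small for the oracle
  list(W = W, alpha = alpha, beta = beta, prior = prior, y = y)
}

# Well-separated three-class rectangle model used by several suites.
rectangle_fixture <- function() {
  make_rectangle_classes(8, c(2, 3, 4), lambda = c(50, 150, 300), alpha = 20)
}
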
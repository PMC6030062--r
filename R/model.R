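#' Negative binomial log pmf (shape/rate parameterization)
#'
#' Log probability mass of the brightness marginal of the Gamma-Poisson
#' model: integrating the Poisson intensity against `Gamma(alpha, rate =
#' beta)` gives `NB(k; alpha, prob = beta / (beta + 1))`, i.e.
#' `Gamma(k + alpha) / (k! Gamma(alpha)) * (beta/(beta+1))^alpha *
#' (1/(beta+1))^k`. Evaluated in log space through `lgamma`, so large and
#' (rounded) non-integer `k` are handled without overflow.
#'
#' @param k non-negative count(s); vectorized.
#' @param alpha positive Gamma shape(s).
#' @param beta positive Gamma rate(s).
#' @return Log pmf value(s); recycled to the common length.
#' @examples
#' nb_log_pmf(0, 1, 1)  # log(0.5)
#' @export
nb_log_pmf <- function(k, alpha, beta) {
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("`alpha` and `beta` must be positive", call. = FALSE)
  }
  lgamma(k + alpha) - lgamma(k + 1) - lgamma(alpha) +
    alpha * (log(beta) - log1p(beta)) - k * log1p(beta)
}

#' Sample stimuli from the Gamma-Poisson generative model
#'
#' For each stimulus a class is drawn from the prior, an intensity
#' `z ~ Gamma(alpha_c, rate = beta_c)`, and each element
#' `y_d ~ Poisson(z * W[c, d])`.
#'
#' @param params a [gp_params] object.
#' @param n number of stimuli to draw.
#' @param seed optional integer seed for reproducibility.
#' @return A [gp_dataset] with `true_c` and `true_z` filled (and `labels`
#'   set equal to `true_c`).
#' @examples
#' p <- gp_params(rbind(c(1, 0), c(0, 1)), alpha = 4, beta = c(2, 0.5))
#' d <- sample_gp_dataset(p, 5, seed = 1)
#' d$brightness
#' @export
sample_gp_dataset <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "gp_params"))
  stopifnot_scalar_count(n)
  if (!is.null(seed)) set.seed(seed)
  C <- nrow(params$W)
  cc <- sample.int(C, n, replace = TRUE, prob = params$prior)
  z <- stats::rgamma(n, shape = params$alpha[cc], rate = params$beta[cc])
  mu <- params$W[cc, , drop = FALSE] * z
  Y <- matrix(stats::rpois(length(mu), mu), nrow = n)
  gp_dataset(Y, labels = cc, true_c = cc, true_z = z)
}

# Per-class log joint weight log P(y, c) up to the y-dependent constant
# shared across classes: log prior + sum_d y_d log W_cd + log NB(yhat).
class_log_weights <- function(y, params) {
  yhat <- sum(y)
  drop(params$logW %*% y) +
    nb_log_pmf(yhat, params$alpha, params$beta) +
    log(params$prior)
}

#' Closed-form joint posterior over class and intensity
#'
#' The posterior factorizes as a class posterior `s` times a per-class Gamma
#' over the intensity with shifted parameters: given class `c`,
#' `z | y, c ~ Gamma(alpha_c + yhat, rate = beta_c + 1)` where
#' `yhat = sum(y)`. The class posterior is proportional to
#' `prior_c * prod_d W[c,d]^y_d * NB(yhat; alpha_c, 1/(beta_c+1))`,
#' evaluated entirely in log space.
#'
#' @param y non-negative stimulus vector of length `D`.
#' @param params a [gp_params] object.
#' @return An object of class `gp_posterior`: list with the class posterior
#'   `s` (simplex vector of length `C`), the per-class intensity posterior
#'   parameters `z_shape = alpha + yhat` and `z_rate = beta + 1`, and the
#'   marginal posterior-mean intensity `z_mean = sum(s * z_shape / z_rate)`.
#' @export
joint_posterior <- function(y, params) {
  stopifnot(inherits(params, "gp_params"))
  if (length(y) != ncol(params$W)) {
    stop("`y` length must match the number of input dimensions", call. = FALSE)
  }
  if (any(y < 0) || any(!is.finite(y))) {
    stop("`y` must be finite and non-negative", call. = FALSE)
  }
  yhat <- sum(y)
  lw <- class_log_weights(y, params)
  s <- exp(lw - logsumexp(lw))
  s <- s / sum(s)
  z_shape <- params$alpha + yhat
  z_rate <- params$beta + 1
  structure(
    list(s = s, z_shape = z_shape, z_rate = z_rate,
         z_mean = sum(s * z_shape / z_rate), yhat = yhat),
    class = "gp_posterior"
  )
}

#' Marginal class posterior
#'
#' Marginalizes the intensity out of the joint posterior; equals the `s`
#' component of [joint_posterior()].
#'
#' @inheritParams joint_posterior
#' @return Simplex vector of length `C`.
#' @export
class_posterior <- function(y, params) {
  joint_posterior(y, params)$s
}

#' Posterior-mean stimulus intensity
#'
#' Marginalizes the unknown class out of the intensity posterior:
#' `sum_c s_c * (alpha_c + yhat) / (beta_c + 1)`.
#'
#' @inheritParams joint_posterior
#' @return Positive scalar posterior mean of `z`.
#' @export
posterior_mean_intensity <- function(y, params) {
  joint_posterior(y, params)$z_mean
}

#' Class responsibilities for a whole dataset
#'
#' Vectorized [class_posterior()] over the rows of a stimulus matrix.
#'
#' @param Y `N x D` non-negative stimulus matrix.
#' @param params a [gp_params] object.
#' @return `N x C` matrix with rows on the simplex.
#' @export
class_responsibilities <- function(Y, params) {
  stopifnot(inherits(params, "gp_params"))
  Y <- as.matrix(Y)
  yhat <- rowSums(Y)
  L <- Y %*% t(params$logW)
  for (c in seq_along(params$alpha)) {
    L[, c] <- L[, c] + nb_log_pmf(yhat, params$alpha[c], params$beta[c]) +
      log(params$prior[c])
  }
  softmax_rows(L)
}

#' Log marginal likelihood of a dataset
#'
#' `sum_n log sum_c P(c) P(y^(n) | c)` with
#' `log P(y | c) = log NB(yhat; alpha_c, 1/(beta_c+1)) + lgamma(yhat + 1) -
#' sum_d lgamma(y_d + 1) + sum_d y_d log W[c,d]` (the multinomial
#' shape factor times the negative binomial brightness marginal).
#'
#' @param data a [gp_dataset] (or non-negative matrix).
#' @param params a [gp_params] object.
#' @return Scalar log likelihood; finite for valid inputs.
#' @export
log_marginal_likelihood <- function(data, params) {
  stopifnot(inherits(params, "gp_params"))
  Y <- if (inherits(data, "gp_dataset")) data$Y else as.matrix(data)
  yhat <- rowSums(Y)
  L <- Y %*% t(params$logW)
  for (c in seq_along(params$alpha)) {
    L[, c] <- L[, c] + nb_log_pmf(yhat, params$alpha[c], params$beta[c]) +
      log(params$prior[c])
  }
  const <- lgamma(yhat + 1) - rowSums(lgamma(Y + 1))
  sum(apply(L, 1L, logsumexp) + const)
}
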
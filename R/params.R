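#' Gamma-Poisson model parameters
#'
#' Container for the parameters of the Gamma-Poisson class/intensity
#' generative model: a stimulus of class `c` is generated by drawing an
#' intensity `z ~ Gamma(alpha_c, rate = beta_c)` and then each element
#' `y_d ~ Poisson(z * W[c, d])`. Rows of the feature matrix `W` are
#' renormalized to sum to one so that the total brightness
#' `yhat = sum(y)` is marginally negative binomial,
#' `NB(yhat; alpha_c, prob = beta_c / (beta_c + 1))`.
#'
#' @param W numeric matrix, `C x D`, non-negative class feature prototypes
#'   (one row per class). Rows are floored at `w_floor` and renormalized to
#'   sum to one.
#' @param alpha positive numeric vector of length `C` (Gamma shapes);
#'   scalars are recycled.
#' @param beta positive numeric vector of length `C` (Gamma rates);
#'   scalars are recycled.
#' @param prior optional class prior on the simplex; defaults to uniform.
#' @param w_floor smallest admissible entry of `W` (keeps `log W` finite).
#'
#' @return An object of class `gp_params`: a list with elements `W`, `logW`,
#'   `alpha`, `beta`, `prior` and the derived mean intensities
#'   `lambda = alpha / beta`.
#' @examples
#' p <- gp_params(W = rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
#'                alpha = c(4, 8), beta = c(0.1, 0.1))
#' p$lambda
#' @export
gp_params <- function(W, alpha, beta, prior = NULL, w_floor = 1e-12) {
  W <- as.matrix(W)
  if (any(!is.finite(W)) || any(W < 0)) {
    stop("`W` must be a finite non-negative matrix", call. = FALSE)
  }
  C <- nrow(W)
  if (any(rowSums(W) <= 0)) stop("each row of `W` needs positive mass", call. = FALSE)
  if (length(alpha) == 1L) alpha <- rep(alpha, C)
  if (length(beta) == 1L) beta <- rep(beta, C)
  if (length(alpha) != C || length(beta) != C) {
    stop("`alpha` and `beta` must have one entry per class", call. = FALSE)
  }
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("`alpha` and `beta` must be positive", call. = FALSE)
  }
  if (is.null(prior)) prior <- rep(1 / C, C)
  if (length(prior) != C || any(prior < 0) || sum(prior) <= 0) {
    stop("`prior` must be a non-negative vector of length C with positive sum",
         call. = FALSE)
  }
  prior <- prior / sum(prior)
  W <- floor_and_normalize_rows(W, w_floor)
  structure(
    list(W = W, logW = log(W), alpha = as.numeric(alpha),
         beta = as.numeric(beta), prior = prior,
         lambda = as.numeric(alpha) / as.numeric(beta)),
    class = "gp_params"
  )
}

#' @export
print.gp_params <- function(x, ...) {
  cat("Gamma-Poisson model parameters\n")
  cat("  classes:", nrow(x$W), " input dimensions:", ncol(x$W), "\n")
  cat("  lambda (mean intensity per class):",
      paste(signif(x$lambda, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Circuit-level parameters
#'
#' Parameters of the two-layer soft winner-take-all circuit that
#' approximates inference in the Gamma-Poisson model: feedforward synapses
#' `W` (one row per class neuron), intrinsic excitabilities `lambda`
#' (each neuron's learned mean input brightness), copy weights `V` linking
#' the class layer to the intensity read-out neuron, and a single shared
#' Gamma rate `beta_shared` defining the read-out gain
#' `K = 1 / (beta_shared + 1)`.
#'
#' @param W numeric `C x D` matrix of non-negative synaptic weights; rows
#'   floored and renormalized to sum to one.
#' @param lambda positive numeric vector of length `C` of excitabilities.
#' @param V positive numeric vector of length `C`; defaults to `lambda`
#'   (its converged value under the copy-weight learning rule).
#' @param beta_shared positive scalar, the shared Gamma rate used by the
#'   intensity read-out.
#' @param w_floor smallest admissible entry of `W`.
#' @return An object of class `gp_circuit` with elements `W`, `logW`,
#'   `lambda`, `V`, `beta_shared` and `K`.
#' @examples
#' circ <- circuit_params(W = rbind(c(0.9, 0.1), c(0.1, 0.9)),
#'                        lambda = c(5, 20), beta_shared = 0.5)
#' circ$K
#' @export
circuit_params <- function(W, lambda, V = lambda, beta_shared, w_floor = 1e-12) {
  W <- as.matrix(W)
  if (any(!is.finite(W)) || any(W < 0)) {
    stop("`W` must be a finite non-negative matrix", call. = FALSE)
  }
  C <- nrow(W)
  if (length(lambda) != C || any(lambda <= 0)) {
    stop("`lambda` must be positive with one entry per class neuron", call. = FALSE)
  }
  if (length(V) != C || any(V <= 0)) {
    stop("`V` must be positive with one entry per class neuron", call. = FALSE)
  }
  if (!is.numeric(beta_shared) || length(beta_shared) != 1L || beta_shared <= 0) {
    stop("`beta_shared` must be a positive scalar", call. = FALSE)
  }
  W <- floor_and_normalize_rows(W, w_floor)
  structure(
    list(W = W, logW = log(W), lambda = as.numeric(lambda),
         V = as.numeric(V), beta_shared = as.numeric(beta_shared),
         K = 1 / (beta_shared + 1)),
    class = "gp_circuit"
  )
}

#' @export
print.gp_circuit <- function(x, ...) {
  cat("Soft-WTA circuit parameters\n")
  cat("  class neurons:", nrow(x$W), " input dimensions:", ncol(x$W), "\n")
  cat("  lambda:", paste(signif(x$lambda, 4), collapse = ", "), "\n")
  cat("  V:     ", paste(signif(x$V, 4), collapse = ", "), "\n")
  cat("  beta_shared:", signif(x$beta_shared, 4), " K:", signif(x$K, 4), "\n")
  invisible(x)
}

#' Build circuit parameters from full model parameters
#'
#' Collapses full Gamma-Poisson parameters to the circuit parameterization:
#' `lambda = alpha / beta`, `V = lambda`, and a single shared rate. If a
#' training dataset is supplied, `beta_shared` is the responsibility-weighted
#' average of per-class method-of-moments estimates of `beta_c` on the
#' brightness values; otherwise it is the prior-weighted mean of `beta`.
#'
#' @param params a [gp_params] object.
#' @param data optional [gp_dataset] used to estimate `beta_shared`.
#' @return A [circuit_params] object.
#' @export
as_circuit <- function(params, data = NULL) {
  stopifnot(inherits(params, "gp_params"))
  beta_shared <- if (is.null(data)) {
    sum(params$prior * params$beta)
  } else {
    estimate_beta_shared(data, params)
  }
  circuit_params(W = params$W, lambda = params$lambda,
                 beta_shared = beta_shared)
}

#' Estimate the shared Gamma rate from data
#'
#' Computes per-class method-of-moments estimates of the Gamma rate from the
#' responsibility-weighted mean and variance of the brightness (NB marginal:
#' mean `m = lambda`, variance `v = lambda + lambda / beta`, so
#' `beta = m / (v - m)`), then averages them weighted by total class
#' responsibility. Under-dispersed classes (`v <= m`, impossible under the
#' model) are capped at `beta = 1e3` (near-Poisson).
#'
#' @param data a [gp_dataset].
#' @param params a [gp_params] object used for the responsibilities.
#' @return Positive scalar estimate of the shared rate.
#' @export
estimate_beta_shared <- function(data, params) {
  S <- class_responsibilities(data$Y, params)
  w <- colSums(S)
  beta_hat <- moment_gamma_rates(data$brightness, S)$beta
  sum(w * beta_hat) / sum(w)
}

# Responsibility-weighted method-of-moments Gamma (alpha, beta) from
# brightness values. S is N x C. Guard: under-dispersion -> beta = 1e3.
moment_gamma_rates <- function(yhat, S, beta_cap = 1e3) {
  w <- colSums(S)
  m <- colSums(S * yhat) / w
  v <- colSums(S * (outer(yhat, m, "-")^2)) / w
  beta <- ifelse(v > m, m / (v - m), beta_cap)
  beta <- pmin(beta, beta_cap)
  list(alpha = beta * m, beta = beta, mean = m, var = v)
}

#' Serialize model or circuit parameters to JSON
#'
#' `gp_params` objects are written with keys `W`, `alpha`, `beta`, `prior`,
#' `format_version`; `gp_circuit` objects with keys `W`, `lambda`, `V`,
#' `beta_shared`, `format_version`.
#'
#' @param x a [gp_params] or [gp_circuit] object.
#' @param path file path to write to.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(x, path) {
  obj <- if (inherits(x, "gp_params")) {
    list(W = unname(x$W), alpha = x$alpha, beta = x$beta, prior = x$prior,
         format_version = 1L)
  } else if (inherits(x, "gp_circuit")) {
    list(W = unname(x$W), lambda = x$lambda, V = x$V,
         beta_shared = x$beta_shared, format_version = 1L)
  } else {
    stop("`x` must be gp_params or gp_circuit", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model or circuit parameters from JSON
#'
#' Dispatches on the keys present: `alpha`/`beta` yields a [gp_params]
#' object, `lambda`/`beta_shared` a [circuit_params] object.
#'
#' @param path file path written by [write_params_json()].
#' @return A [gp_params] or [gp_circuit] object.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$W)
  if (!is.null(obj$alpha)) {
    gp_params(W, alpha = obj$alpha, beta = obj$beta, prior = obj$prior)
  } else {
    circuit_params(W, lambda = obj$lambda, V = obj$V %||% obj$lambda,
                   beta_shared = obj$beta_shared)
  }
}
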
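#' Input currents of the class-neuron layer (log synapses)
#'
#' In the Poisson limit of the negative binomial brightness marginal, the
#' class posterior becomes a softmax over the currents
#' `I_c = sum_d y_d ln(W[c,d] * lambda_c) - lambda_c`.
#'
#' @param y non-negative stimulus vector of length `D`.
#' @param circuit a [circuit_params] object.
#' @return Numeric vector of length `C` of input currents.
#' @export
currents_log <- function(y, circuit) {
  stopifnot(inherits(circuit, "gp_circuit"))
  if (length(y) != ncol(circuit$W)) {
    stop("`y` length must match the number of input dimensions", call. = FALSE)
  }
  drop(circuit$logW %*% y) + sum(y) * log(circuit$lambda) - circuit$lambda
}

#' Input currents of the class-neuron layer (linearized synapses)
#'
#' Linear approximation of the logarithmic synaptic nonlinearity:
#' `I_c = sum_d W[c,d] y_d + yhat * log(lambda_c) - lambda_c`.
#'
#' @inheritParams currents_log
#' @return Numeric vector of length `C` of input currents.
#' @export
currents_linear <- function(y, circuit) {
  stopifnot(inherits(circuit, "gp_circuit"))
  if (length(y) != ncol(circuit$W)) {
    stop("`y` length must match the number of input dimensions", call. = FALSE)
  }
  drop(circuit$W %*% y) + sum(y) * log(circuit$lambda) - circuit$lambda
}

#' Soft winner-take-all activation
#'
#' Softmax over input currents with max subtraction; the fixed point of
#' competitive soft-WTA dynamics in the class layer.
#'
#' @param I finite numeric vector of input currents.
#' @return Simplex vector of the same length.
#' @examples
#' soft_wta(c(0, log(3)))  # c(0.25, 0.75)
#' @export
soft_wta <- function(I) {
  if (any(is.na(I))) stop("currents must not be NaN", call. = FALSE)
  e <- exp(I - max(I))
  e / sum(e)
}

#' Circuit responsibilities for a whole dataset
#'
#' Vectorized soft-WTA output over the rows of a stimulus matrix.
#'
#' @param Y `N x D` non-negative stimulus matrix.
#' @param circuit a [circuit_params] object.
#' @param mode `"log"` for [currents_log()] or `"linear"` for
#'   [currents_linear()].
#' @return `N x C` matrix with rows on the simplex.
#' @export
circuit_responsibilities <- function(Y, circuit, mode = c("log", "linear")) {
  stopifnot(inherits(circuit, "gp_circuit"))
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  yhat <- rowSums(Y)
  Wterm <- if (mode == "log") Y %*% t(circuit$logW) else Y %*% t(circuit$W)
  I <- Wterm + outer(yhat, log(circuit$lambda)) -
    matrix(circuit$lambda, nrow(Y), length(circuit$lambda), byrow = TRUE)
  softmax_rows(I)
}

#' Linear intensity read-out of the second layer
#'
#' The intensity neuron combines total input drive with the class-layer
#' output: `s_z = K * (yhat - sum_c s_c * V_c)` with `K = 1/(beta_shared +
#' 1)`. By default the locally learned copy weights `V` are used; with
#' `use_lambda = TRUE` the read-out uses the intrinsic excitabilities
#' directly (an "oracle" mode that assumes non-local access to `lambda`).
#'
#' @param yhat non-negative total stimulus brightness.
#' @param s simplex vector of class-layer activations.
#' @param circuit a [circuit_params] object.
#' @param use_lambda use `lambda` instead of the copy weights `V`.
#' @return Scalar read-out (the circuit's contrastive-stress estimate).
#' @export
intensity_readout <- function(yhat, s, circuit, use_lambda = FALSE) {
  stopifnot(inherits(circuit, "gp_circuit"))
  if (length(s) != length(circuit$lambda)) {
    stop("`s` must have one entry per class neuron", call. = FALSE)
  }
  if (abs(sum(s) - 1) > 1e-6) {
    stop("`s` must lie on the simplex", call. = FALSE)
  }
  ref <- if (use_lambda) circuit$lambda else circuit$V
  circuit$K * (yhat - sum(s * ref))
}
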
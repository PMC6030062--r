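#' Bayes-optimal contrastive stress
#'
#' Contrastive stress of a stimulus is defined as the posterior-mean
#' intensity minus the posterior-weighted class-mean intensity:
#' `E = <z>_{P(z|y)} - <lambda_c>_{P(c|y)}`. A stimulus that is exactly as
#' intense as is typical for its (inferred) class has stress 0.
#'
#' @param y non-negative stimulus vector.
#' @param params a [gp_params] object.
#' @return Scalar stress estimate.
#' @export
stress_bayes <- function(y, params) {
  post <- joint_posterior(y, params)
  post$z_mean - sum(post$s * params$lambda)
}

#' Circuit contrastive-stress estimate
#'
#' The second-layer read-out `s_z = K (yhat - sum_c s_c V_c)` with `s` from
#' the soft-WTA class layer; the neural approximation of [stress_bayes()].
#'
#' @param y non-negative stimulus vector.
#' @param circuit a [circuit_params] object.
#' @param use_lambda pass `TRUE` to read out through `lambda` instead of the
#'   learned copy weights `V` (oracle mode).
#' @param mode current mode for the class layer (`"log"` or `"linear"`).
#' @return Scalar stress estimate.
#' @export
stress_circuit <- function(y, circuit, use_lambda = FALSE, mode = c("log", "linear")) {
  mode <- match.arg(mode)
  I <- if (mode == "log") currents_log(y, circuit) else currents_linear(y, circuit)
  intensity_readout(sum(y), soft_wta(I), circuit, use_lambda = use_lambda)
}

#' Naive stress estimate for a sentence
#'
#' Per-utterance brightness minus the mean brightness over the sentence,
#' ignoring class structure entirely. Always sums to zero.
#'
#' @param sentence a [gp_dataset] of utterances.
#' @return Numeric vector, one value per utterance.
#' @export
stress_naive <- function(sentence) {
  stopifnot(inherits(sentence, "gp_dataset"))
  if (nrow(sentence$Y) < 1) stop("empty sentence", call. = FALSE)
  sentence$brightness - mean(sentence$brightness)
}

#' Enhanced naive stress estimate
#'
#' Approximates the expected intensity of an utterance by its brightness and
#' compares it to the posterior-weighted class-mean intensity:
#' `E = yhat - sum_c s_c lambda_c`. Uses the exact class posterior, so it
#' has access to the class statistics but maps brightness to intensity
#' sub-optimally.
#'
#' @inheritParams stress_bayes
#' @return Scalar stress estimate.
#' @export
stress_enhanced_naive <- function(y, params) {
  s <- class_posterior(y, params)
  sum(y) - sum(s * params$lambda)
}

#' Evaluate all stress estimators on a sentence
#'
#' Computes, per utterance, the Bayes-optimal stress `E_B` and enhanced
#' naive stress `E_EN` (from the full model parameters), the circuit
#' estimate `E_IP` and the circuit's class prediction (from the circuit
#' parameters), and the naive estimate `E_N` (brightness centering), plus
#' the root-mean-square distance of the latter three estimators from `E_B`.
#'
#' @param sentence a [gp_dataset] of utterances.
#' @param params a [gp_params] object (for `E_B` and `E_EN`).
#' @param circuit a [circuit_params] object (for `E_IP` and classification).
#' @return An object of class `sentence_result`: list with `table` (data
#'   frame: `utterance`, `predicted_class`, `E_B`, `E_IP`, `E_N`, `E_EN`,
#'   plus `true_class` when the sentence is labeled) and `rms` (named
#'   vector `E_IP`, `E_N`, `E_EN` of RMS distances from `E_B`).
#' @export
evaluate_sentence <- function(sentence, params, circuit) {
  stopifnot(inherits(sentence, "gp_dataset"), inherits(params, "gp_params"),
            inherits(circuit, "gp_circuit"))
  N <- nrow(sentence$Y)
  E_B <- E_EN <- E_IP <- numeric(N)
  pred <- integer(N)
  for (n in seq_len(N)) {
    y <- sentence$Y[n, ]
    post <- joint_posterior(y, params)
    E_B[n] <- post$z_mean - sum(post$s * params$lambda)
    E_EN[n] <- post$yhat - sum(post$s * params$lambda)
    s_circ <- soft_wta(currents_log(y, circuit))
    E_IP[n] <- intensity_readout(post$yhat, s_circ, circuit)
    pred[n] <- which.max(s_circ)
  }
  E_N <- stress_naive(sentence)
  rms <- c(E_IP = sqrt(mean((E_IP - E_B)^2)),
           E_N = sqrt(mean((E_N - E_B)^2)),
           E_EN = sqrt(mean((E_EN - E_B)^2)))
  tab <- data.frame(utterance = seq_len(N), predicted_class = pred,
                    E_B = E_B, E_IP = E_IP, E_N = E_N, E_EN = E_EN)
  if (!is.null(sentence$labels)) tab$true_class <- sentence$labels
  structure(list(table = tab, rms = rms), class = "sentence_result")
}

#' @export
print.sentence_result <- function(x, ...) {
  cat("Sentence stress evaluation (", nrow(x$table), " utterances)\n", sep = "")
  print(x$table, digits = 4)
  cat("RMS distance from Bayes-optimal estimate:\n")
  print(signif(x$rms, 4))
  invisible(x)
}

#' Fit the semi-supervised label map
#'
#' Builds the Bayesian read-out classifier from a small labeled subset:
#' `conditional[l, c]` is proportional to the smoothed responsibility mass
#' that label `l` received from class neuron `c`, normalized per column
#' (columns are `P(label | class neuron)`).
#'
#' @param responses `N x C` matrix of class-layer responses (rows on the
#'   simplex), one row per labeled example.
#' @param labels integer labels in `1..L` aligned with the rows.
#' @param smoothing small positive Laplace smoothing constant.
#' @return An object of class `gp_label_map`: list with the `L x C`
#'   column-stochastic matrix `conditional` and `n_labels`.
#' @export
fit_label_map <- function(responses, labels, smoothing = 1e-6) {
  responses <- as.matrix(responses)
  if (nrow(responses) == 0) stop("no labeled examples", call. = FALSE)
  if (length(labels) != nrow(responses)) {
    stop("`labels` must align with the rows of `responses`", call. = FALSE)
  }
  L <- max(labels)
  C <- ncol(responses)
  cond <- matrix(smoothing, L, C)
  for (n in seq_along(labels)) {
    cond[labels[n], ] <- cond[labels[n], ] + responses[n, ]
  }
  cond <- sweep(cond, 2L, colSums(cond), "/")
  structure(list(conditional = cond, n_labels = L), class = "gp_label_map")
}

#' Classify a class-layer response through the label map
#'
#' `P(l | s)` proportional to `sum_c conditional[l, c] * s_c`, normalized.
#'
#' @param s simplex vector of class-layer responses (or an `N x C` matrix).
#' @param map a [fit_label_map()] object.
#' @return For a vector `s`: the label posterior (length `L`). For a matrix:
#'   an `N x L` matrix of label posteriors. Predictions are the `argmax`
#'   (lowest index wins ties, as with `which.max`).
#' @export
classify_responses <- function(s, map) {
  stopifnot(inherits(map, "gp_label_map"))
  if (is.matrix(s)) {
    P <- s %*% t(map$conditional)
    return(P / rowSums(P))
  }
  p <- drop(map$conditional %*% s)
  p / sum(p)
}

#' Semi-supervised classification accuracy
#'
#' Runs the full protocol used to score a learned representation: compute
#' circuit responses for all stimuli, fit the label map on exactly `L`
#' labeled training examples (allocated with at least one example per
#' class, remainder at random), and report held-out accuracy of the argmax
#' label prediction.
#'
#' @param train,test labeled [gp_dataset]s.
#' @param circuit a [circuit_params] object.
#' @param L total number of labeled training examples to use.
#' @param seed integer seed for the labeled-subset draw.
#' @param mode current mode for the class layer.
#' @return List with `accuracy`, the fitted `map`, and `labeled_idx`.
#' @export
classifier_accuracy <- function(train, test, circuit, L = 30, seed = 1,
                                mode = c("log", "linear")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(train$labels), !is.null(test$labels))
  classes <- sort(unique(train$labels))
  if (L < length(classes)) {
    stop("`L` must be at least the number of distinct labels", call. = FALSE)
  }
  set.seed(seed)
  idx <- unlist(lapply(classes, function(l) {
    cand <- which(train$labels == l)
    cand[sample.int(length(cand), 1)]
  }))
  remaining <- setdiff(seq_len(nrow(train$Y)), idx)
  extra <- L - length(idx)
  if (extra > 0) idx <- c(idx, sample(remaining, extra))
  S_lab <- circuit_responsibilities(train$Y[idx, , drop = FALSE], circuit, mode)
  map <- fit_label_map(S_lab, train$labels[idx])
  S_test <- circuit_responsibilities(test$Y, circuit, mode)
  P <- classify_responses(S_test, map)
  pred <- max.col(P, ties.method = "first")
  list(accuracy = mean(pred == test$labels), map = map, labeled_idx = idx)
}
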
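#' End-to-end digit experiment: intensity-aware vs shape-only learning
#'
#' Reproduces, at desk scale on synthetic digit-like images, the comparison
#' between the intensity-aware circuit (Hebbian + intrinsic plasticity on
#' inputs whose class-brightness structure is preserved or enhanced) and a
#' shape-only control (the same circuit with `lambda` clamped to a common
#' constant and inputs normalized to a constant mass, so brightness carries
#' no information). Both representations are learned without labels and
#' scored with the semi-supervised read-out classifier on exactly `L`
#' labeled examples.
#'
#' @param n_train,n_test number of training / held-out images.
#' @param n_classes number of digit classes (labels `1..n_classes`).
#' @param C number of class neurons.
#' @param L labeled-example budget for the read-out classifier.
#' @param epochs training epochs.
#' @param eps_w,eps_lambda learning rates for the intensity-aware circuit
#'   (defaults are desk-scale values suited to a few hundred images; see the
#'   methods vignette).
#' @param A_ip mass of the shape-normalized image before class-dependent
#'   brightening (intensity-aware pipeline).
#' @param A_sa mass of the shape-only normalization (control pipeline).
#' @param overlap prototype shape overlap across classes (0..1); higher
#'   values make shape less informative and brightness more valuable.
#' @param seed integer seed controlling data generation, training and the
#'   labeled-subset draw.
#' @return An object of class `digit_experiment`: list with `accuracy_ip`,
#'   `accuracy_shape`, the two fits (`fit_ip`, `fit_shape`), per-neuron
#'   matched classes and mean class brightnesses (`lambda_targets`), and the
#'   final relative error of each matched neuron's `lambda`
#'   (`lambda_rel_error`).
#' @export
run_digit_experiment <- function(n_train = 600, n_test = 400, n_classes = 10,
                                 C = 10, L = 30, epochs = 20,
                                 eps_w = 1e-4, eps_lambda = 5e-3,
                                 A_ip = 450, A_sa = 500, overlap = 0.85,
                                 seed = 1) {
  raw_train <- synth_digit_images(n_train, n_classes = n_classes,
                                  overlap = overlap, seed = seed)
  raw_test <- synth_digit_images(n_test, n_classes = n_classes,
                                 overlap = overlap,
                                 prototypes = raw_train$prototypes,
                                 seed = seed + 1000L)
  v <- brightening_offsets()[seq_len(n_classes)]
  ref <- mean(rowSums(raw_train$images))

  Y_ip_train <- brighten_class_dependent(raw_train$images, raw_train$labels,
                                         A = A_ip, v = v)
  Y_ip_test <- brighten_class_dependent(raw_test$images, raw_test$labels,
                                        A = A_ip, v = v, reference_mean = ref)
  train_ip <- gp_dataset(Y_ip_train, labels = raw_train$labels)
  test_ip <- gp_dataset(Y_ip_test, labels = raw_test$labels)

  Y_sa_train <- normalize_shape_only(raw_train$images, A = A_sa)
  Y_sa_test <- normalize_shape_only(raw_test$images, A = A_sa)
  train_sa <- gp_dataset(Y_sa_train, labels = raw_train$labels)
  test_sa <- gp_dataset(Y_sa_test, labels = raw_test$labels)

  cfg_ip <- learning_config(eps_w = eps_w, eps_lambda = eps_lambda,
                            epochs = epochs, seed = seed,
                            init_mode = "datapoint_spread", n_restarts = 3)
  fit_ip <- train_circuit(train_ip, C, cfg_ip)

  # Shape-only control: same codebase, lambda clamped to the common input
  # mass (inputs all sum to A_sa, so lambda is uninformative by design).
  cfg_sa <- learning_config(eps_w = eps_w, eps_lambda = 0, epochs = epochs,
                            seed = seed,
                            init_mode = "datapoint_spread", n_restarts = 3)
  fit_sa <- train_circuit(train_sa, C, cfg_sa)
  fit_sa$circuit$lambda <- rep(A_sa, C)
  fit_sa$circuit <- circuit_params(W = fit_sa$circuit$W,
                                   lambda = rep(A_sa, C),
                                   beta_shared = fit_sa$circuit$beta_shared)

  acc_ip <- classifier_accuracy(train_ip, test_ip, fit_ip$circuit,
                                L = L, seed = seed)
  acc_sa <- classifier_accuracy(train_sa, test_sa, fit_sa$circuit,
                                L = L, seed = seed)

  # Match neurons to classes by majority responsibility mass on training
  # data; lambda should approach the matched class's mean brightness.
  S <- circuit_responsibilities(train_ip$Y, fit_ip$circuit)
  mass <- t(vapply(seq_len(n_classes), function(l) {
    colSums(S[train_ip$labels == l, , drop = FALSE])
  }, numeric(C)))
  neuron_class <- apply(mass, 2L, which.max)
  class_brightness <- vapply(seq_len(n_classes), function(l) {
    mean(train_ip$brightness[train_ip$labels == l])
  }, numeric(1))
  lambda_targets <- class_brightness[neuron_class]
  lambda_rel_error <- abs(fit_ip$circuit$lambda - lambda_targets) / lambda_targets

  structure(
    list(accuracy_ip = acc_ip$accuracy, accuracy_shape = acc_sa$accuracy,
         fit_ip = fit_ip, fit_shape = fit_sa,
         neuron_class = neuron_class, lambda_targets = lambda_targets,
         lambda_rel_error = lambda_rel_error, seed = seed),
    class = "digit_experiment"
  )
}

#' @export
print.digit_experiment <- function(x, ...) {
  cat("Digit experiment (seed", x$seed, ")\n")
  cat("  intensity-aware circuit accuracy:", signif(x$accuracy_ip, 4), "\n")
  cat("  shape-only control accuracy:    ", signif(x$accuracy_shape, 4), "\n")
  cat("  max relative error of matched lambda:",
      signif(max(x$lambda_rel_error), 3), "\n")
  invisible(x)
}

#' End-to-end sentence experiment: contrastive-stress estimation
#'
#' Trains a `C = 4` circuit on synthetic logatome spectrograms (no labels),
#' fits full Gamma-Poisson parameters by batch EM on the training set
#' (initialized from the trained circuit) to obtain the Bayes-optimal
#' reference, assembles a 10-utterance test sentence with at least two
#' examples of each class, and evaluates all four stress estimators.
#'
#' @param n_per_class training samples per logatome class.
#' @param n_test_per_class held-out samples per class (sentence pool).
#' @param epochs training epochs.
#' @param eps_w,eps_lambda,eps_v learning rates (the intrinsic-plasticity
#'   rate follows the printed spectrogram-experiment value `1e-2`; the
#'   synaptic and copy-weight rates are desk-scale choices, see the methods
#'   vignette).
#' @param em_iters batch-EM refinement iterations for the reference model.
#' @param n_utterances sentence length.
#' @param seed integer seed.
#' @return An object of class `sentence_experiment`: list with `result`
#'   (the [evaluate_sentence()] output), `fit` (the trained circuit),
#'   `em_params` (the EM reference parameters) and `seed`.
#' @export
run_sentence_experiment <- function(n_per_class = 60, n_test_per_class = 20,
                                    epochs = 10, eps_w = 2e-5,
                                    eps_lambda = 1e-2, eps_v = 1e-2,
                                    em_iters = 10,
                                    n_utterances = 10, seed = 1) {
  gen <- make_logatome_params(seed = seed)
  train <- make_synthetic_logatomes(n_per_class, params = gen, seed = seed)
  test <- make_synthetic_logatomes(n_test_per_class, params = gen,
                                   seed = seed + 1000L)

  cfg <- learning_config(eps_w = eps_w, eps_lambda = eps_lambda,
                         eps_v = eps_v, epochs = epochs, seed = seed,
                         init_mode = "datapoint_spread", n_restarts = 3)
  fit <- train_circuit(train, nrow(gen$W), cfg)

  # Full-model reference for the Bayes-optimal estimator: Gamma parameters
  # fitted by batch EM, initialized from the trained circuit.
  S <- circuit_responsibilities(train$Y, fit$circuit)
  mm <- moment_gamma_rates(train$brightness, S)
  init <- gp_params(W = fit$circuit$W, alpha = mm$alpha, beta = mm$beta)
  em <- run_em(train, init, iters = em_iters)

  sentence <- build_sentence(test, n_utterances = n_utterances, seed = seed)
  res <- evaluate_sentence(sentence, em$params, fit$circuit)

  structure(list(result = res, fit = fit, em_params = em$params, seed = seed),
            class = "sentence_experiment")
}

#' @export
print.sentence_experiment <- function(x, ...) {
  cat("Sentence experiment (seed", x$seed, ")\n")
  print(x$result)
  invisible(x)
}
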
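#' Online learning configuration
#'
#' Bundles learning rates, initialization scheme, and run controls for
#' online circuit training. The default rates are the values used for
#' unnormalized digit images in the source experiments (`eps_w = 1e-5`,
#' `eps_lambda = 1e-4`); learning is robust to moderate changes and the
#' desk-scale experiment drivers in this package use larger rates suited to
#' their smaller corpora.
#'
#' @param eps_w positive Hebbian learning rate for the synapses `W`.
#' @param eps_lambda positive intrinsic-plasticity rate for `lambda`.
#' @param eps_v positive rate for the copy weights `V`.
#' @param epochs number of passes over the training set.
#' @param seed integer seed controlling initialization and shuffling.
#' @param init_mode `"datapoint"` initializes each `W` row from a randomly
#'   chosen training stimulus; `"datapoint_spread"` also uses training
#'   stimuli but selects them sequentially with probability proportional to
#'   the squared distance from the stimuli already chosen (k-means++-style
#'   seeding, which avoids seeding two neurons inside one tight class when
#'   `C` equals the true class count); `"mean_plus_poisson_noise"` uses the
#'   mean stimulus plus `0.1 * Poisson(1)` noise per element.
#' @param lambda_init `"brightness"` sets each neuron's initial `lambda` to
#'   the brightness of its initialization stimulus (datapoint mode) or the
#'   mean training brightness; a numeric `c(lo, hi)` draws uniform values
#'   in that range (the brightness-enhanced digit setup used 550..850).
#' @param current_mode `"log"` or `"linear"` input currents during learning.
#' @param shuffle_each_epoch reshuffle the presentation order every epoch.
#' @param n_restarts number of independent training runs (differing in
#'   initialization and presentation order); the run with the highest final
#'   Poisson-limit log likelihood is kept. Multi-start selection is the
#'   usual guard against initialization-dependent local optima in mixture
#'   fitting.
#' @return An object of class `gp_learning_config`.
#' @export
learning_config <- function(eps_w = 1e-5, eps_lambda = 1e-4, eps_v = 1e-3,
                            epochs = 10, seed = 1,
                            init_mode = c("datapoint", "datapoint_spread",
                                          "mean_plus_poisson_noise"),
                            lambda_init = "brightness",
                            current_mode = c("log", "linear"),
                            shuffle_each_epoch = TRUE,
                            n_restarts = 1) {
  if (eps_w < 0 || eps_lambda < 0 || eps_v < 0) {
    stop("learning rates must be non-negative", call. = FALSE)
  }
  stopifnot_scalar_count(epochs, "epochs")
  init_mode <- match.arg(init_mode)
  current_mode <- match.arg(current_mode)
  if (is.numeric(lambda_init)) {
    if (length(lambda_init) != 2L || lambda_init[1] >= lambda_init[2]) {
      stop("numeric `lambda_init` must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  } else if (!identical(lambda_init, "brightness")) {
    stop("`lambda_init` must be \"brightness\" or a numeric range", call. = FALSE)
  }
  stopifnot_scalar_count(n_restarts, "n_restarts")
  structure(
    list(eps_w = eps_w, eps_lambda = eps_lambda, eps_v = eps_v,
         epochs = as.integer(epochs), seed = as.integer(seed),
         init_mode = init_mode, lambda_init = lambda_init,
         current_mode = current_mode,
         shuffle_each_epoch = isTRUE(shuffle_each_epoch),
         n_restarts = as.integer(n_restarts)),
    class = "gp_learning_config"
  )
}

# Single plasticity step given precomputed responsibilities s.
# Returns updated (W, lambda, V); floors lambda, V at 1e-6 and W at 0.
plasticity_step <- function(W, lambda, V, y, s, eps_w, eps_lambda, eps_v) {
  yhat <- sum(y)
  W <- W + eps_w * s * (matrix(y, nrow(W), ncol(W), byrow = TRUE) - lambda * W)
  W[W < 0] <- 0
  lambda <- pmax(lambda + eps_lambda * s * (yhat - lambda), 1e-6)
  V <- pmax(V + eps_v * s * (yhat - V), 1e-6)
  list(W = W, lambda = lambda, V = V)
}

#' One online Hebbian / intrinsic-plasticity update
#'
#' Computes the class-layer activation `s` by soft-WTA over the configured
#' currents, then applies the local updates
#' `dW[c,d] = eps_w * s_c * (y_d - lambda_c * W[c,d])`,
#' `dlambda_c = eps_lambda * s_c * (yhat - lambda_c)`, and
#' `dV_c = eps_v * s_c * (e - V_c)` with the second layer clamped to the
#' feedforward drive `e = yhat` during learning. `lambda` and `V` are
#' floored at `1e-6` and `W` at 0.
#'
#' @param state a [circuit_params] object.
#' @param y non-negative stimulus vector.
#' @param cfg a [learning_config()].
#' @return Updated [circuit_params] (same `beta_shared`).
#' @export
online_update <- function(state, y, cfg = learning_config()) {
  stopifnot(inherits(state, "gp_circuit"), inherits(cfg, "gp_learning_config"))
  I <- if (cfg$current_mode == "log") currents_log(y, state) else currents_linear(y, state)
  s <- soft_wta(I)
  upd <- plasticity_step(state$W, state$lambda, state$V, y, s,
                         cfg$eps_w, cfg$eps_lambda, cfg$eps_v)
  circuit_params(W = upd$W, lambda = upd$lambda, V = upd$V,
                 beta_shared = state$beta_shared)
}

# Poisson-limit data log likelihood under circuit parameters (uniform class
# prior): sum_n [logsumexp_c I_c(y_n) - log C - sum_d lgamma(y_nd + 1)].
circuit_log_likelihood <- function(Y, W, lambda) {
  Y <- as.matrix(Y)
  logW <- log(pmax(W, 1e-12))
  I <- Y %*% t(logW) + outer(rowSums(Y), log(lambda)) -
    matrix(lambda, nrow(Y), length(lambda), byrow = TRUE)
  sum(apply(I, 1L, logsumexp)) - nrow(Y) * log(length(lambda)) -
    sum(lgamma(Y + 1))
}

#' Train the circuit online
#'
#' Initializes the circuit per the configuration and applies
#' [online_update()] for every stimulus, for `cfg$epochs` passes over the
#' training set (order reshuffled each epoch when configured). After
#' training, `beta_shared` is set to the responsibility-weighted
#' method-of-moments estimate from the training brightnesses.
#'
#' @param data a [gp_dataset]; labels are never used.
#' @param C number of class neurons; must not exceed the number of stimuli.
#' @param cfg a [learning_config()].
#' @return A list of class `gp_fit` with elements `circuit` (the trained
#'   [circuit_params]), `history` (data frame with one row per epoch: the
#'   Poisson-limit log likelihood and each neuron's `lambda`), and `config`.
#' @export
train_circuit <- function(data, C, cfg = learning_config()) {
  stopifnot(inherits(data, "gp_dataset"), inherits(cfg, "gp_learning_config"))
  if (cfg$n_restarts == 1L) return(train_circuit_once(data, C, cfg))
  best <- NULL
  for (k in seq_len(cfg$n_restarts)) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + (k - 1L) * 10007L
    fit <- train_circuit_once(data, C, cfg_k)
    ll <- utils::tail(fit$history$loglik, 1)
    if (is.null(best) || ll > best_ll) {
      best <- fit
      best_ll <- ll
    }
  }
  best$config <- cfg
  best
}

train_circuit_once <- function(data, C, cfg) {
  stopifnot(inherits(data, "gp_dataset"), inherits(cfg, "gp_learning_config"))
  stopifnot_scalar_count(C, "C")
  Y <- data$Y
  N <- nrow(Y)
  D <- ncol(Y)
  if (C > N) stop("`C` must not exceed the number of stimuli", call. = FALSE)
  set.seed(cfg$seed)

  if (cfg$init_mode %in% c("datapoint", "datapoint_spread")) {
    if (cfg$init_mode == "datapoint") {
      pick <- sample.int(N, C)
    } else {
      # Seeding distances on shape (row-normalized stimuli) and brightness,
      # each block scaled to unit total variance so neither cue dominates.
      shape <- Y / pmax(data$brightness, 1e-12)
      sv <- sum(apply(shape, 2L, stats::var))
      bv <- stats::var(data$brightness)
      X <- cbind(if (sv > 0) shape / sqrt(sv) else shape,
                 if (bv > 0) data$brightness / sqrt(bv) else data$brightness)
      pick <- sample.int(N, 1)
      for (i in seq_len(C - 1L)) {
        d2 <- vapply(seq_len(N), function(n) {
          min(colSums((t(X[pick, , drop = FALSE]) - X[n, ])^2))
        }, numeric(1))
        d2[pick] <- 0
        pick <- c(pick, sample.int(N, 1, prob = d2 / sum(d2)))
      }
    }
    W <- floor_and_normalize_rows(Y[pick, , drop = FALSE])
    lambda <- if (is.numeric(cfg$lambda_init)) {
      stats::runif(C, cfg$lambda_init[1], cfg$lambda_init[2])
    } else {
      pmax(data$brightness[pick], 1e-6)
    }
  } else {
    mu <- colMeans(Y)
    W <- t(vapply(seq_len(C),
                  function(i) mu + 0.1 * stats::rpois(D, 1),
                  numeric(D)))
    W <- floor_and_normalize_rows(W)
    lambda <- if (is.numeric(cfg$lambda_init)) {
      stats::runif(C, cfg$lambda_init[1], cfg$lambda_init[2])
    } else {
      rep(mean(data$brightness), C)
    }
  }
  V <- rep(mean(data$brightness), C)
  logW <- log(pmax(W, 1e-12))

  history <- data.frame(epoch = seq_len(cfg$epochs), loglik = NA_real_)
  lam_hist <- matrix(NA_real_, cfg$epochs, C)

  for (ep in seq_len(cfg$epochs)) {
    ord <- if (cfg$shuffle_each_epoch) sample.int(N) else seq_len(N)
    for (n in ord) {
      y <- Y[n, ]
      yhat <- data$brightness[n]
      I <- if (cfg$current_mode == "log") {
        drop(logW %*% y) + yhat * log(lambda) - lambda
      } else {
        drop(W %*% y) + yhat * log(lambda) - lambda
      }
      s <- soft_wta(I)
      upd <- plasticity_step(W, lambda, V, y, s,
                             cfg$eps_w, cfg$eps_lambda, cfg$eps_v)
      W <- upd$W
      lambda <- upd$lambda
      V <- upd$V
      if (cfg$eps_w > 0) logW <- log(pmax(W, 1e-12))
    }
    history$loglik[ep] <- circuit_log_likelihood(Y, W, lambda)
    lam_hist[ep, ] <- lambda
  }
  colnames(lam_hist) <- paste0("lambda", seq_len(C))
  history <- cbind(history, as.data.frame(lam_hist))

  S <- softmax_rows(Y %*% t(log(pmax(W, 1e-12))) +
                      outer(data$brightness, log(lambda)) -
                      matrix(lambda, N, C, byrow = TRUE))
  mm <- moment_gamma_rates(data$brightness, S)
  w <- colSums(S)
  beta_shared <- sum(w * mm$beta) / sum(w)

  structure(
    list(circuit = circuit_params(W = W, lambda = lambda, V = V,
                                  beta_shared = beta_shared),
         history = history, config = cfg),
    class = "gp_fit"
  )
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Trained soft-WTA circuit (", nrow(x$circuit$W), " neurons, ",
      x$config$epochs, " epochs)\n", sep = "")
  cat("  final lambda:", paste(signif(x$circuit$lambda, 4), collapse = ", "), "\n")
  cat("  final log likelihood:", signif(utils::tail(x$history$loglik, 1), 6), "\n")
  invisible(x)
}

#' One batch expectation-maximization step
#'
#' E-step: exact class responsibilities under the current parameters.
#' M-step: `lambda_c` is the responsibility-weighted mean brightness,
#' `W[c,d] = sum_n s_nc y_nd / (lambda_c sum_n s_nc)` (rows sum to one by
#' construction), `(alpha_c, beta_c)` by responsibility-weighted method of
#' moments on the brightness (under-dispersed classes capped at
#' `beta = 1e3`), and the prior is the mean responsibility. A class whose
#' total responsibility falls below `1e-8` is reinitialized from the
#' stimulus the model currently explains worst, with a warning.
#'
#' @param data a [gp_dataset].
#' @param params a [gp_params] object.
#' @return Updated [gp_params].
#' @export
batch_em_step <- function(data, params) {
  stopifnot(inherits(data, "gp_dataset"), inherits(params, "gp_params"))
  Y <- data$Y
  yhat <- data$brightness
  S <- class_responsibilities(Y, params)
  w <- colSums(S)

  empty <- which(w < 1e-8)
  if (length(empty) > 0) {
    warning("reinitializing ", length(empty), " empty class(es)")
    worst <- order(apply(S, 1L, max))
    for (i in seq_along(empty)) {
      n <- worst[i]
      S[n, ] <- 0
      S[n, empty[i]] <- 1
    }
    w <- colSums(S)
  }

  lambda <- colSums(S * yhat) / w
  W <- t(S) %*% Y / (lambda * w)
  mm <- moment_gamma_rates(yhat, S)
  gp_params(W = W, alpha = mm$alpha, beta = mm$beta, prior = w / sum(w))
}

#' Run batch EM to (near) convergence
#'
#' Iterates [batch_em_step()], tracking the log marginal likelihood.
#'
#' @param data a [gp_dataset].
#' @param params initial [gp_params].
#' @param iters maximum number of EM iterations.
#' @param tol stop when the log-likelihood improvement falls below `tol`
#'   (set `tol = 0` to always run `iters` steps).
#' @return List with `params` (final [gp_params]) and `loglik` (vector of
#'   log marginal likelihoods, one per completed iteration).
#' @export
run_em <- function(data, params, iters = 50, tol = 0) {
  ll <- numeric(0)
  for (i in seq_len(iters)) {
    params <- batch_em_step(data, params)
    ll[i] <- log_marginal_likelihood(data, params)
    if (tol > 0 && i > 1 && ll[i] - ll[i - 1] < tol) break
  }
  list(params = params, loglik = ll)
}

#' Expected online updates over a dataset (fixed-point check)
#'
#' Computes the responsibility-weighted mean of the Hebbian and
#' intrinsic-plasticity updates over a dataset,
#' `mean_dlambda[c] = sum_n s_nc (yhat_n - lambda_c) / sum_n s_nc` and
#' `mean_dW[c,d] = sum_n s_nc (y_nd - lambda_c W[c,d]) / sum_n s_nc`
#' (learning rates factored out). At a batch-EM fixed point both vanish,
#' which is the fixed-point correspondence between the online rules and EM.
#'
#' @param data a [gp_dataset].
#' @param state a [gp_params] object (exact responsibilities) or a
#'   [circuit_params] object (soft-WTA responsibilities, log currents).
#' @return List with `mean_dW` (`C x D`), `mean_dlambda` (length `C`),
#'   `rel_dlambda = max |mean_dlambda| / lambda`, and `rel_dW` = the
#'   largest row-L1 norm of `mean_dW` (rows of `W` sum to one, so this is
#'   relative to the row mass).
#' @export
check_fixed_point <- function(data, state) {
  stopifnot(inherits(data, "gp_dataset"))
  if (inherits(state, "gp_params")) {
    S <- class_responsibilities(data$Y, state)
    W <- state$W
    lambda <- state$lambda
  } else if (inherits(state, "gp_circuit")) {
    S <- circuit_responsibilities(data$Y, state, mode = "log")
    W <- state$W
    lambda <- state$lambda
  } else {
    stop("`state` must be gp_params or gp_circuit", call. = FALSE)
  }
  w <- colSums(S)
  mean_dlambda <- colSums(S * data$brightness) / w - lambda
  mean_dW <- t(S) %*% data$Y / w - lambda * W
  list(mean_dW = mean_dW, mean_dlambda = mean_dlambda,
       rel_dlambda = max(abs(mean_dlambda) / lambda),
       rel_dW = max(rowSums(abs(mean_dW))))
}

#' Align learned classes to reference classes
#'
#' Greedy best-permutation matching of learned rows of `W` (or learned
#' `lambda`) to reference rows by smallest row-L1 distance; used to compare
#' recovered parameters with ground truth up to label permutation.
#'
#' @param W_learned,W_ref `C x D` matrices.
#' @return Integer permutation `perm` such that `W_learned[perm[c], ]`
#'   corresponds to `W_ref[c, ]`.
#' @export
match_classes <- function(W_learned, W_ref) {
  C <- nrow(W_ref)
  cost <- matrix(0, C, C)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      cost[i, j] <- sum(abs(W_learned[j, ] - W_ref[i, ]))
    }
  }
  perm <- integer(C)
  taken <- rep(FALSE, C)
  for (i in order(apply(cost, 1L, min))) {
    j <- order(cost[i, ])
    j <- j[!taken[j]][1]
    perm[i] <- j
    taken[j] <- TRUE
  }
  perm
}
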
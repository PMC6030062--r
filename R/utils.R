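# Internal numerical helpers.

# log(sum(exp(x))) with max subtraction; returns -Inf for all -Inf input.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax of a matrix of log-weights.
softmax_rows <- function(L) {
  m <- apply(L, 1L, max)
  E <- exp(L - m)
  E / rowSums(E)
}

# Floor a non-negative weight matrix and renormalize rows to sum to one.
floor_and_normalize_rows <- function(W, floor = 1e-12) {
  W <- pmax(W, floor)
  W / rowSums(W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(n, what = "n") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n)) {
    stop("`", what, "` must be a positive integer", call. = FALSE)
  }
}
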
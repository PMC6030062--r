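#' Stimulus dataset container
#'
#' Bundles a matrix of non-negative stimulus vectors (rows = stimuli,
#' columns = input dimensions) with the per-stimulus brightness
#' `yhat = rowSums(Y)`, optional integer class labels, and optional
#' ground-truth latents (class and intensity) when the data are synthetic.
#'
#' @param Y numeric `N x D` matrix of non-negative stimulus vectors.
#' @param labels optional integer class labels in `1..C`.
#' @param true_c optional ground-truth class indices.
#' @param true_z optional ground-truth positive intensities.
#' @return An object of class `gp_dataset`: a list with elements `Y`,
#'   `brightness`, and any of `labels`, `true_c`, `true_z` supplied.
#' @examples
#' d <- gp_dataset(matrix(c(1, 2, 0, 3), 2, 2), labels = c(1L, 2L))
#' d$brightness
#' @export
gp_dataset <- function(Y, labels = NULL, true_c = NULL, true_z = NULL) {
  Y <- as.matrix(Y)
  if (any(!is.finite(Y)) || any(Y < 0)) {
    stop("`Y` must be a finite non-negative matrix", call. = FALSE)
  }
  n <- nrow(Y)
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != n) {
      stop("`", what, "` must have one entry per stimulus", call. = FALSE)
    }
    x
  }
  labels <- check_len(labels, "labels")
  if (!is.null(labels)) {
    if (any(labels != round(labels)) || any(labels < 1)) {
      stop("`labels` must be positive integers", call. = FALSE)
    }
    labels <- as.integer(labels)
  }
  structure(
    list(Y = Y, brightness = rowSums(Y), labels = labels,
         true_c = check_len(true_c, "true_c"),
         true_z = check_len(true_z, "true_z")),
    class = "gp_dataset"
  )
}

#' @export
print.gp_dataset <- function(x, ...) {
  cat("Stimulus dataset:", nrow(x$Y), "stimuli x", ncol(x$Y), "dimensions\n")
  cat("  brightness range:", paste(signif(range(x$brightness), 4), collapse = " .. "), "\n")
  if (!is.null(x$labels)) {
    cat("  labels:", length(unique(x$labels)), "distinct classes\n")
  }
  invisible(x)
}

#' Subset a dataset by stimulus index
#'
#' @param data a [gp_dataset].
#' @param idx integer index vector of stimuli to keep (order preserved).
#' @return A [gp_dataset] with the selected rows and matching labels/latents.
#' @export
subset_dataset <- function(data, idx) {
  stopifnot(inherits(data, "gp_dataset"))
  gp_dataset(data$Y[idx, , drop = FALSE],
             labels = data$labels[idx],
             true_c = data$true_c[idx],
             true_z = data$true_z[idx])
}

#' Read and write stimulus datasets as delimited text
#'
#' Datasets are stored with one row per stimulus, a header naming the input
#' dimensions (`d1..dD`), and an optional trailing `label` column holding
#' 1-based class labels.
#'
#' @param data a [gp_dataset].
#' @param path file path; `.tsv` extension selects tab separation.
#' @return `write_dataset`: `path` invisibly. `read_dataset`: a [gp_dataset].
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "gp_dataset"))
  df <- as.data.frame(data$Y)
  names(df) <- paste0("d", seq_len(ncol(data$Y)))
  if (!is.null(data$labels)) df$label <- data$labels
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  gp_dataset(as.matrix(df), labels = labels)
}

#' Scale continuous stimuli into the count domain
#'
#' Likelihood evaluation under the Poisson observation model is exact for
#' integer data. Continuous inputs (e.g. log-mel spectrograms) are first
#' multiplied by a gain and rounded to the nearest non-negative integer.
#'
#' @param Y non-negative numeric matrix or vector.
#' @param gain positive multiplier applied before rounding.
#' @return Matrix or vector of non-negative integers (as numeric).
#' @export
to_counts <- function(Y, gain = 1) {
  if (gain <= 0) stop("`gain` must be positive", call. = FALSE)
  pmax(round(Y * gain), 0)
}
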
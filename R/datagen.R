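#' Rectangle-class model parameters
#'
#' Builds Gamma-Poisson parameters whose class prototypes are flattened
#' 2-D images of white boxes of varying sizes on a black background (each
#' row normalized to sum to one), with class-specific intensity
#' distributions: by default class 1 is the dimmest and the last class the
#' brightest. Boxes are placed in distinct corners of the image (cycling
#' through the four corners), so supports of up to four classes with box
#' sides at most `image_side / 2` are disjoint.
#'
#' @param image_side side of the square image in pixels.
#' @param box_sizes integer vector of box side lengths, one per class.
#' @param lambda mean intensity per class (`alpha / beta`).
#' @param alpha Gamma shape per class (scalar recycled); together with
#'   `lambda` determines `beta = alpha / lambda`.
#' @param prior optional class prior.
#' @return A [gp_params] object with `length(box_sizes)` classes and
#'   `image_side^2` input dimensions.
#' @examples
#' p <- make_rectangle_classes(8, c(2, 3, 4), lambda = c(50, 150, 300))
#' rowSums(p$W)
#' @export
make_rectangle_classes <- function(image_side = 8, box_sizes = c(2, 3, 4),
                                   lambda = c(50, 150, 300), alpha = 20,
                                   prior = NULL) {
  C <- length(box_sizes)
  if (length(lambda) != C) {
    stop("`lambda` must have one entry per class", call. = FALSE)
  }
  if (any(box_sizes > image_side)) {
    stop("boxes must fit inside the image", call. = FALSE)
  }
  if (length(alpha) == 1L) alpha <- rep(alpha, C)
  corners <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  W <- matrix(0, C, image_side^2)
  for (c in seq_len(C)) {
    b <- box_sizes[c]
    corner <- corners[[(c - 1L) %% 4L + 1L]]
    r0 <- if (corner[1] == 1) 1L else image_side - b + 1L
    c0 <- if (corner[2] == 1) 1L else image_side - b + 1L
    img <- matrix(0, image_side, image_side)
    img[r0:(r0 + b - 1L), c0:(c0 + b - 1L)] <- 1
    W[c, ] <- as.vector(img)
  }
  gp_params(W, alpha = alpha, beta = alpha / lambda, prior = prior)
}

#' Synthetic raw digit-like images
#'
#' Generates raw grayscale images emulating a hand-written-character corpus:
#' each class has a random sparse prototype sharing a common background
#' component with the other classes (`overlap` controls how confusable the
#' shapes are), each image scales its class prototype by a Gamma-distributed
#' brightness factor with mean `brightness_mean[l]` (so the relative
#' brightness `f` has mean ~1 when all class means are 1), and pixel-level
#' Poisson noise is added.
#'
#' @param n number of images.
#' @param n_classes number of classes; labels cycle through `1..n_classes`,
#'   so the batch is balanced whenever `n` is a multiple of `n_classes`.
#' @param side image side in pixels (`D = side^2`).
#' @param overlap fraction (0..1) of each prototype shared across classes.
#' @param brightness_mean per-class mean of the image brightness factor
#'   (scalar recycled; default 1 for every class).
#' @param brightness_shape Gamma shape of the brightness factor (larger =
#'   tighter spread; 25 gives ~20% relative spread).
#' @param mass expected raw pixel mass of an image at brightness factor 1.
#' @param prototypes optional `n_classes x side^2` matrix of class
#'   prototypes from a previous call; supply it to draw further samples
#'   (e.g. a held-out test set) from the same classes.
#' @param seed integer seed.
#' @return List with `images` (`n x side^2` non-negative matrix), `labels`
#'   (balanced, cycling), and `prototypes` (`n_classes x side^2`).
#' @export
synth_digit_images <- function(n, n_classes = 10, side = 20, overlap = 0.5,
                               brightness_mean = 1, brightness_shape = 25,
                               mass = 400, prototypes = NULL, seed = 1) {
  stopifnot_scalar_count(n)
  set.seed(seed)
  D <- side^2
  if (length(brightness_mean) == 1L) {
    brightness_mean <- rep(brightness_mean, n_classes)
  }
  if (is.null(prototypes)) {
    common <- stats::runif(D) * stats::rbinom(D, 1, 0.4)
    proto <- matrix(0, n_classes, D)
    for (l in seq_len(n_classes)) {
      own <- stats::runif(D) * stats::rbinom(D, 1, 0.15)
      p <- (1 - overlap) * own / sum(own) + overlap * common / sum(common)
      proto[l, ] <- p / sum(p)
    }
  } else {
    proto <- as.matrix(prototypes)
    stopifnot(nrow(proto) == n_classes, ncol(proto) == D)
  }
  labels <- rep_len(seq_len(n_classes), n)
  b <- stats::rgamma(n, shape = brightness_shape,
                     rate = brightness_shape / brightness_mean[labels])
  mu <- proto[labels, , drop = FALSE] * (b * mass)
  images <- matrix(stats::rpois(length(mu), mu), nrow = n)
  list(images = images, labels = labels, prototypes = proto)
}

#' Shape-only input normalization
#'
#' Normalizes a raw non-negative image to total mass `A` with every element
#' at least 1: `y_d = (A - D) * raw_d / sum(raw) + 1`. This removes all
#' brightness information (the transform is invariant to rescaling the raw
#' input) and is the preprocessing required by shape-only circuits.
#'
#' @param raw non-negative vector (one image) or matrix (one image per row)
#'   with positive sum(s).
#' @param A target total mass; must exceed the input dimensionality `D`.
#' @return Normalized vector or matrix; rows sum to `A`, all elements >= 1.
#' @examples
#' normalize_shape_only(c(1, 1, 1, 1), A = 8)  # all pixels 2, sum 8
#' @export
normalize_shape_only <- function(raw, A) {
  if (is.matrix(raw)) {
    D <- ncol(raw)
    if (A <= D) stop("`A` must exceed the input dimensionality", call. = FALSE)
    rs <- rowSums(raw)
    if (any(rs <= 0)) stop("every image needs positive total mass", call. = FALSE)
    return((A - D) * raw / rs + 1)
  }
  D <- length(raw)
  if (A <= D) stop("`A` must exceed the input dimensionality", call. = FALSE)
  s <- sum(raw)
  if (s <= 0) stop("input must have positive total mass", call. = FALSE)
  (A - D) * raw / s + 1
}

#' Brightness-preserving normalization
#'
#' Normalizes each image to mass `A` as in [normalize_shape_only()], then
#' rescales the foreground by the image's relative brightness
#' `f = sum(raw) / mean(sum(raw))` (computed against `reference_mean` when
#' supplied, e.g. the training-set mean for held-out data):
#' `y = (y_SA - 1) * f + 1`. Background pixels stay at exactly 1 and the
#' batch-mean brightness factor is 1, so class-specific brightness structure
#' in the raw data is preserved while the shape is normalized.
#'
#' @param raw_batch non-negative matrix, one raw image per row.
#' @param A target mass of the shape-normalized image.
#' @param reference_mean optional external mean raw brightness.
#' @return Matrix of transformed images (all elements >= 1).
#' @export
brighten_preserving <- function(raw_batch, A, reference_mean = NULL) {
  raw_batch <- as.matrix(raw_batch)
  ySA <- normalize_shape_only(raw_batch, A)
  bright <- rowSums(raw_batch)
  f <- bright / (reference_mean %||% mean(bright))
  (ySA - 1) * f + 1
}

#' Printed class-dependent brightening offsets
#'
#' The ten per-label foreground amplification offsets `v(l)` used to induce
#' a strong class-brightness dependence in a ten-class image corpus.
#'
#' @return Numeric vector of length 10.
#' @export
brightening_offsets <- function() {
  c(2.3, 3.4, 3.3, 4.0, 4.8, 5.3, 5.9, 6.7, 6.9, 7.5)
}

#' Class-dependent foreground brightening
#'
#' Amplifies image foregrounds depending on both the image's own relative
#' brightness `f` and its class label:
#' `y = (y_SA - 1) * (f + v(l)) + 1`, where `y_SA` is the
#' [normalize_shape_only()] output at mass `A`. Background pixels (value 1
#' after normalization) map to exactly 1; the total brightness of an image
#' becomes `(A - D) * (f + v(l)) + D`, so a balanced batch with mean `f = 1`
#' has mean brightness `(A - D) * (1 + mean(v)) + D`.
#'
#' @param raw_batch non-negative matrix, one raw image per row.
#' @param labels integer labels in `1..length(v)` aligned with the rows.
#' @param A target mass of the shape-normalized image (default 450).
#' @param v per-label brightening offsets (default [brightening_offsets()]).
#' @param reference_mean optional external mean raw brightness.
#' @return Matrix of transformed images (all elements >= 1).
#' @export
brighten_class_dependent <- function(raw_batch, labels, A = 450,
                                     v = brightening_offsets(),
                                     reference_mean = NULL) {
  raw_batch <- as.matrix(raw_batch)
  if (length(labels) != nrow(raw_batch)) {
    stop("`labels` must align with the rows of `raw_batch`", call. = FALSE)
  }
  if (any(labels < 1) || any(labels > length(v))) {
    stop("labels out of range of `v`", call. = FALSE)
  }
  ySA <- normalize_shape_only(raw_batch, A)
  bright <- rowSums(raw_batch)
  f <- bright / (reference_mean %||% mean(bright))
  (ySA - 1) * (f + v[labels]) + 1
}

#' Trim a spectrogram around its high-energy center of mass
#'
#' Finds the `n_top_bins` time bins with the highest total energy across
#' frequencies, takes the energy-weighted center of mass (COM) of their time
#' indices (rounded to the nearest column, ties toward the earlier column),
#' and keeps the window of `2 * half_width + 1` columns centered there.
#' The spectrogram is discarded with reason `"edge"` when the window falls
#' outside the recording (the sound sits too close to its beginning or end)
#' and with reason `"energy"` when the window retains less than
#' `energy_keep_fraction` of the total energy.
#'
#' @param spec numeric matrix, frequency channels x time bins.
#' @param n_top_bins number of highest-energy time bins for the COM
#'   (if the recording is shorter than this, all bins are used, with a
#'   message).
#' @param half_width number of columns kept on each side of the COM.
#' @param energy_keep_fraction minimum retained energy fraction.
#' @return List with `kept` (logical); if kept, `spec` (the trimmed matrix),
#'   `com` (the center column), and `energy_fraction`; if discarded,
#'   `reason` (`"edge"` or `"energy"`) and `energy_fraction` where defined.
#' @export
trim_spectrogram <- function(spec, n_top_bins = 20, half_width = 50,
                             energy_keep_fraction = 0.65) {
  spec <- as.matrix(spec)
  Tn <- ncol(spec)
  if (Tn < 1) stop("spectrogram needs at least one time bin", call. = FALSE)
  energy <- colSums(spec)
  k <- n_top_bins
  if (Tn < n_top_bins) {
    message("spectrogram shorter than `n_top_bins`; using all ", Tn, " bins")
    k <- Tn
  }
  # bins tied with the k-th largest energy all enter the COM (their weights
  # decide); with distinct energies this is exactly the top k bins
  thr <- sort(energy, decreasing = TRUE)[k]
  top <- which(energy >= thr)
  com <- sum(top * energy[top]) / sum(energy[top])
  center <- ceiling(com - 0.5)  # nearest column, ties toward earlier
  lo <- center - half_width
  hi <- center + half_width
  if (lo < 1 || hi > Tn) {
    return(list(kept = FALSE, reason = "edge", com = center))
  }
  frac <- sum(energy[lo:hi]) / sum(energy)
  if (frac < energy_keep_fraction) {
    return(list(kept = FALSE, reason = "energy", com = center,
                energy_fraction = frac))
  }
  list(kept = TRUE, spec = spec[, lo:hi, drop = FALSE], com = center,
       energy_fraction = frac)
}

#' Logatome-like spectrogram model parameters
#'
#' Class prototypes are distinct two-dimensional Gaussian blobs on a small
#' time-frequency grid (one blob per logatome class, centers spread over
#' the grid), normalized to sum to one; intensities are Gamma with
#' class-specific means, emulating logatome classes whose loudness differs
#' systematically.
#'
#' @param n_classes number of logatome classes.
#' @param n_mel frequency channels of the template grid.
#' @param n_time time bins of the template grid.
#' @param lambda mean intensity (brightness) per class.
#' @param beta Gamma rate, shared across classes by default (the circuit's
#'   intensity read-out assumes the class rates are similar, so the
#'   generator emulates that regime); class shapes are `alpha = beta *
#'   lambda`.
#' @param seed integer seed for the blob placement.
#' @return A [gp_params] object with `n_mel * n_time` input dimensions.
#' @export
make_logatome_params <- function(n_classes = 4, n_mel = 16, n_time = 16,
                                 lambda = c(300, 500, 800, 1200),
                                 beta = 0.1, seed = 1) {
  if (length(lambda) != n_classes) {
    stop("`lambda` must have one entry per class", call. = FALSE)
  }
  set.seed(seed)
  if (length(beta) == 1L) beta <- rep(beta, n_classes)
  alpha <- beta * lambda
  W <- matrix(0, n_classes, n_mel * n_time)
  # Distinct templates: classes occupy separate time slots and alternate
  # between low and high frequency bands, with small seeded jitter.
  mel_centers <- ifelse(seq_len(n_classes) %% 2 == 1, 0.3, 0.7) * n_mel +
    stats::runif(n_classes, -0.05, 0.05) * n_mel
  time_centers <- (seq_len(n_classes) - 0.5) / n_classes * n_time +
    stats::runif(n_classes, -0.03, 0.03) * n_time
  for (c in seq_len(n_classes)) {
    blob <- outer(seq_len(n_mel), seq_len(n_time), function(m, t) {
      exp(-((m - mel_centers[c])^2 / (2 * (n_mel / 6)^2) +
              (t - time_centers[c])^2 / (2 * (n_time / (2.5 * n_classes))^2)))
    })
    W[c, ] <- as.vector(blob)
  }
  gp_params(W, alpha = alpha, beta = beta)
}

#' Synthetic logatome dataset
#'
#' Samples a balanced labeled dataset of logatome-like spectrograms from
#' [make_logatome_params()] (or supplied parameters): per sample a
#' class-specific Gamma intensity scales the class template and element-wise
#' Poisson noise is added; with `poisson = FALSE` the noiseless scaled
#' template is rounded instead.
#'
#' @param n_per_class samples per class (balanced by construction).
#' @param params optional [gp_params]; default [make_logatome_params()].
#' @param seed integer seed.
#' @param poisson add Poisson observation noise (default) or round the
#'   noiseless scaled template.
#' @return A [gp_dataset] with `labels`, `true_c`, `true_z` filled; the
#'   generating parameters are attached as attribute `"params"`.
#' @export
make_synthetic_logatomes <- function(n_per_class = 125, params = NULL,
                                     seed = 1, poisson = TRUE) {
  stopifnot_scalar_count(n_per_class, "n_per_class")
  if (is.null(params)) params <- make_logatome_params(seed = seed)
  set.seed(seed + 1L)
  C <- nrow(params$W)
  cc <- rep(seq_len(C), each = n_per_class)
  z <- stats::rgamma(length(cc), shape = params$alpha[cc],
                     rate = params$beta[cc])
  mu <- params$W[cc, , drop = FALSE] * z
  Y <- if (poisson) {
    matrix(stats::rpois(length(mu), mu), nrow = length(cc))
  } else {
    round(mu)
  }
  out <- gp_dataset(Y, labels = cc, true_c = cc, true_z = z)
  attr(out, "params") <- params
  out
}

#' Assemble a test sentence from held-out utterances
#'
#' Draws `n_utterances` stimuli from a labeled test set such that every
#' class appears at least twice, then randomizes their order. This is the
#' construction used for the contrastive-stress evaluation sentence.
#'
#' @param test_set a labeled [gp_dataset].
#' @param n_utterances sentence length; must be at least twice the number
#'   of classes.
#' @param seed integer seed.
#' @return A [gp_dataset] of `n_utterances` stimuli (labels and any
#'   ground-truth latents carried along).
#' @export
build_sentence <- function(test_set, n_utterances = 10, seed = 1) {
  stopifnot(inherits(test_set, "gp_dataset"))
  if (is.null(test_set$labels)) {
    stop("`test_set` must be labeled", call. = FALSE)
  }
  classes <- sort(unique(test_set$labels))
  if (n_utterances < 2 * length(classes)) {
    stop("sentence too short to hold two examples of each class", call. = FALSE)
  }
  if (any(table(factor(test_set$labels, levels = classes)) < 2)) {
    stop("every class needs at least two test examples", call. = FALSE)
  }
  set.seed(seed)
  idx <- unlist(lapply(classes, function(l) {
    sample(which(test_set$labels == l), 2)
  }))
  remaining <- setdiff(seq_len(nrow(test_set$Y)), idx)
  extra <- n_utterances - length(idx)
  if (extra > length(remaining)) {
    stop("not enough test examples for the requested sentence length",
         call. = FALSE)
  }
  if (extra > 0) idx <- c(idx, sample(remaining, extra))
  subset_dataset(test_set, sample(idx))
}
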
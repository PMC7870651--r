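#' Synthetic classification benchmark with planted feature roles
#'
#' Generates a class-balanced table in which every feature has a known role:
#' \describe{
#'   \item{positive}{class-conditional Gaussians whose class means are
#'     separated by `effect_size * noise_sd` — the features a selector
#'     should recover.}
#'   \item{neutral}{label-independent Gaussian noise.}
#'   \item{negative}{features carrying class structure for one shared random
#'     relabeling of the samples — coherent but misleading signal that can
#'     actively degrade a learner, not mere noise.}
#' }
#'
#' @param n_samples number of samples.
#' @param n_positive,n_neutral,n_negative counts of each feature role.
#' @param n_classes number of classes, default 2.
#' @param effect_size standardized separation between adjacent class means
#'   of a positive feature, default 2.
#' @param noise_sd within-class standard deviation, default 1.
#' @param balance optional class proportions (summing to 1); default equal.
#' @param redundancy number of positive features (out of `n_positive`) that
#'   are noisy copies of another positive feature instead of independent
#'   signal, default 0.
#' @param seed integer seed; the table is a pure function of the arguments.
#' @return List with `table` (a [feature_table()]) and `truth`, the three
#'   ground-truth index sets (`positive`, `neutral`, `negative`) which
#'   partition `1:n_features`.
#' @export
synth_classification <- function(n_samples, n_positive, n_neutral,
                                 n_negative, n_classes = 2, effect_size = 2,
                                 noise_sd = 1, balance = NULL,
                                 redundancy = 0, seed = 1) {
  if (n_samples < 2 * n_classes) {
    stop("need at least 2 samples per class")
  }
  if (effect_size < 0 || noise_sd <= 0) stop("invalid effect/noise spec")
  if (redundancy > max(n_positive - 1, 0)) {
    stop("redundancy cannot exceed n_positive - 1")
  }
  p <- n_positive + n_neutral + n_negative
  if (p < 1) stop("at least one feature is required")
  set.seed(seed)

  if (is.null(balance)) balance <- rep(1 / n_classes, n_classes)
  if (abs(sum(balance) - 1) > 1e-8) stop("balance must sum to 1")
  sizes <- floor(balance * n_samples)
  rem <- n_samples - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  y <- factor(rep(paste0("C", seq_len(n_classes)), times = sizes))

  class_id <- as.integer(y)
  x <- matrix(0, n_samples, p)
  pos_idx <- seq_len(n_positive)
  neu_idx <- seq_len(n_neutral) + n_positive
  neg_idx <- seq_len(n_negative) + n_positive + n_neutral

  n_indep <- n_positive - redundancy
  for (j in seq_len(n_indep)) {
    mu <- (class_id - 1) * effect_size * noise_sd
    x[, pos_idx[j]] <- stats::rnorm(n_samples, mu, noise_sd)
  }
  for (j in seq_len(redundancy)) {
    src <- pos_idx[((j - 1) %% n_indep) + 1]
    x[, pos_idx[n_indep + j]] <- x[, src] + stats::rnorm(n_samples, 0, noise_sd / 2)
  }
  for (j in neu_idx) x[, j] <- stats::rnorm(n_samples, 0, noise_sd)
  if (n_negative > 0) {
    fake_id <- class_id[sample.int(n_samples)]  # one shared relabeling
    for (j in neg_idx) {
      mu <- (fake_id - 1) * effect_size * noise_sd
      x[, j] <- stats::rnorm(n_samples, mu, noise_sd)
    }
  }

  colnames(x) <- paste0(
    rep(c("pos", "neu", "neg"), c(n_positive, n_neutral, n_negative)),
    sequence(c(n_positive, n_neutral, n_negative)))

  list(table = feature_table(x, y, task = "classification"),
       truth = list(positive = pos_idx, neutral = neu_idx,
                    negative = as.integer(neg_idx)))
}

#' Synthetic regression benchmark with planted feature roles
#'
#' The target is the unit-coefficient sum of the positive features plus
#' Gaussian noise.  Neutral features are independent noise; negative
#' features track a random permutation of the target, so they look
#' target-correlated marginally while being misleading for prediction.
#'
#' @inheritParams synth_classification
#' @param noise_sd standard deviation of the target noise, default 1.
#' @return List with `table` (regression [feature_table()]) and `truth`.
#' @export
synth_regression <- function(n_samples, n_positive, n_neutral, n_negative,
                             noise_sd = 1, redundancy = 0, seed = 1) {
  if (n_samples < 4) stop("need at least 4 samples")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (redundancy > max(n_positive - 1, 0)) {
    stop("redundancy cannot exceed n_positive - 1")
  }
  p <- n_positive + n_neutral + n_negative
  if (p < 1) stop("at least one feature is required")
  set.seed(seed)

  x <- matrix(stats::rnorm(n_samples * p), n_samples, p)
  pos_idx <- seq_len(n_positive)
  neu_idx <- seq_len(n_neutral) + n_positive
  neg_idx <- seq_len(n_negative) + n_positive + n_neutral

  n_indep <- n_positive - redundancy
  for (j in seq_len(redundancy)) {
    src <- pos_idx[((j - 1) %% n_indep) + 1]
    x[, pos_idx[n_indep + j]] <- x[, src] + stats::rnorm(n_samples, 0, 0.5)
  }
  y <- if (n_positive > 0) rowSums(x[, pos_idx, drop = FALSE]) else
    numeric(n_samples)
  y <- y + stats::rnorm(n_samples, 0, noise_sd)
  if (n_negative > 0) {
    yp <- y[sample.int(n_samples)]
    sdy <- stats::sd(yp); if (sdy == 0) sdy <- 1
    for (j in neg_idx) {
      x[, j] <- yp / sdy + stats::rnorm(n_samples, 0, 0.5)
    }
  }
  colnames(x) <- make.unique(
    paste0(rep(c("pos", "neu", "neg"),
               c(n_positive, n_neutral, n_negative)),
           sequence(c(n_positive, n_neutral, n_negative))))

  list(table = feature_table(x, y, task = "regression"),
       truth = list(positive = pos_idx, neutral = neu_idx,
                    negative = as.integer(neg_idx)))
}

#' Precision and recall of a selected set against the planted positives
#'
#' @param selected integer vector of selected 1-based feature indices.
#' @param truth the `truth` element of a synthetic benchmark.
#' @return Named vector `c(precision = ..., recall = ...)`.
#' @export
recovery_metrics <- function(selected, truth) {
  pos <- truth$positive
  if (length(pos) == 0) stop("recall undefined: empty positive set")
  hit <- length(intersect(selected, pos))
  c(precision = if (length(selected) == 0) 0 else hit / length(selected),
    recall = hit / length(pos))
}
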
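#' Build confusion counts from predictions or raw counts
#'
#' Either pass `truth` and `pred` (factors over the same levels) to build the
#' full contingency table with per-class one-vs-rest counts, or pass the raw
#' binary counts `tp`, `tn`, `fp`, `fn` directly.
#'
#' @param truth,pred observed and predicted class labels.
#' @param tp,tn,fp,fn raw binary counts (used when `truth` is missing).
#' @return An object of class `confusion_counts`: the pooled contingency
#'   table, per-class `tp`/`tn`/`fp`/`fn`, and the total count.
#' @export
confusion_counts <- function(truth = NULL, pred = NULL,
                             tp = NULL, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(truth)) {
    stopifnot(!is.null(tp), !is.null(tn), !is.null(fp), !is.null(fn))
    if (min(tp, tn, fp, fn) < 0) stop("counts must be non-negative")
    tab <- matrix(c(tp, fn, fp, tn), 2, 2,
                  dimnames = list(truth = c("pos", "neg"),
                                  pred = c("pos", "neg")))
    per_class <- data.frame(class = c("pos", "neg"),
                            tp = c(tp, tn), tn = c(tn, tp),
                            fp = c(fp, fn), fn = c(fn, fp))
  } else {
    truth <- factor(truth)
    pred <- factor(pred, levels = levels(truth))
    if (length(truth) != length(pred)) stop("truth and pred lengths differ")
    tab <- table(truth = truth, pred = pred)
    lev <- levels(truth)
    per_class <- do.call(rbind, lapply(seq_along(lev), function(i) {
      tp <- tab[i, i]
      fn <- sum(tab[i, -i])
      fp <- sum(tab[-i, i])
      tn <- sum(tab) - tp - fn - fp
      data.frame(class = lev[i], tp = tp, tn = tn, fp = fp, fn = fn)
    }))
  }
  structure(list(table = tab, per_class = per_class, total = sum(tab)),
            class = "confusion_counts")
}

#' Classification accuracy from confusion counts
#'
#' The optimizer's fitness for classification: the fraction of correctly
#' classified samples, (TP + TN) / (TP + TN + FP + FN) in the binary case and
#' the trace of the contingency table over its total in general.
#'
#' @param counts a [confusion_counts()] object.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$total == 0) stop("undefined metric: no scored samples")
  sum(diag(counts$table)) / counts$total
}

#' Full classification metric panel
#'
#' Sensitivity, specificity, precision, false-positive rate, accuracy,
#' F-measure and Cohen's kappa.  For two classes the one-vs-rest counts of
#' the first ("positive") class are used; with more classes SEN/SPC/PRE/FPR/F
#' are macro-averaged one-vs-rest while ACC and kappa come from the pooled
#' contingency table.  Zero-denominator cells are reported as 0 and flagged
#' in the `degenerate` attribute.
#'
#' @param counts a [confusion_counts()] object.
#' @return Named numeric vector with elements `SEN`, `SPC`, `PRE`, `FPR`,
#'   `ACC`, `F_measure`, `C_kappa`.
#' @export
panel_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$total == 0) stop("undefined metric: no scored samples")
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; return(0) }
    num / den
  }
  one_class <- function(row) {
    sen <- safe_div(row$tp, row$tp + row$fn)
    spc <- safe_div(row$tn, row$tn + row$fp)
    pre <- safe_div(row$tp, row$tp + row$fp)
    fpr <- safe_div(row$fp, row$fp + row$tn)
    f <- if (pre + sen == 0) { degenerate <<- TRUE; 0 } else 2 * pre * sen / (pre + sen)
    c(SEN = sen, SPC = spc, PRE = pre, FPR = fpr, F_measure = f)
  }
  pc <- counts$per_class
  if (nrow(pc) == 2 && identical(pc$class[1], "pos") ||
      nrow(counts$table) == 2) {
    m <- one_class(pc[1, ])
  } else {
    rows <- lapply(seq_len(nrow(pc)), function(i) one_class(pc[i, ]))
    m <- colMeans(do.call(rbind, rows))
  }
  acc <- accuracy(counts)
  out <- c(m[c("SEN", "SPC", "PRE", "FPR")], ACC = acc,
           F_measure = unname(m["F_measure"]),
           C_kappa = cohens_kappa(counts$table))
  attr(out, "degenerate") <- degenerate
  out
}

#' Cohen's kappa from a contingency table
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e) where p_o is observed
#' agreement and p_e the agreement expected from the marginals.  Returns 1
#' for perfect agreement even when p_e = 1 (single-cell table).
#'
#' @param tab square contingency table, truth in rows, prediction in columns.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0) stop("undefined metric: empty table")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic: the probability that a randomly chosen positive scores above a
#' randomly chosen negative, with ties contributing 1/2.  Invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores per-sample real-valued scores (higher = more positive).
#' @param labels binary labels; the larger level / value is the positive
#'   class, or pass a logical vector (`TRUE` = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) != 2) stop("undefined metric: need exactly 2 classes")
    pos <- labels == levels(droplevels(labels))[2]
  } else {
    pos <- as.logical(labels)
  }
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) stop("undefined metric: both classes must be present")
  r <- rank(scores)  # mean ranks handle ties as 1/2 contributions
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Regression metric pair
#'
#' Root-mean-squared error and the Pearson correlation between predicted and
#' real targets, the two criteria reported for regression tasks.
#'
#' @param pred,real equal-length numeric vectors.
#' @return Named vector `c(RMSE = ..., correlation = ...)`.
#' @export
regression_metrics <- function(pred, real) {
  if (length(pred) != length(real) || length(pred) == 0) {
    stop("pred and real must have equal non-zero length")
  }
  rmse <- sqrt(mean((pred - real)^2))
  if (stats::sd(real) == 0) stop("undefined metric: zero-variance real labels")
  if (stats::sd(pred) == 0) {
    # constant predictions carry no ranking information
    corr <- 0
  } else {
    corr <- stats::cor(pred, real)
  }
  c(RMSE = rmse, correlation = corr)
}
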
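#' Build a cross-validation plan
#'
#' Assigns every sample to one of `k` folds.  Classification folds are
#' stratified by label; fold sizes differ by at most one.  A plan is a value:
#' re-using the same plan makes every subset evaluation during a search
#' comparable and deterministic.
#'
#' @param table a [feature_table()] (or a label vector).
#' @param k number of folds, default 5.
#' @param seed integer seed for the fold assignment.
#' @return Object of class `cv_plan` with `k`, `folds` (per-sample fold id)
#'   and `seed`.
#' @export
cv_plan <- function(table, k = 5, seed = 1) {
  labels <- if (inherits(table, "feature_table")) table$labels else table
  n <- length(labels)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than samples")
  folds <- integer(n)
  set.seed(seed)
  fill <- integer(k)
  groups <- if (is.factor(labels)) split(seq_len(n), labels) else list(seq_len(n))
  for (g in groups) {
    g <- g[sample.int(length(g))]
    for (i in g) {
      cand <- which(fill == min(fill))
      f <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      folds[i] <- f
      fill[f] <- fill[f] + 1L
    }
  }
  structure(list(k = as.integer(k), folds = folds, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Support-vector-machine learner contract
#'
#' The default wrapper learner: an RBF-kernel SVM (libsvm via \pkg{e1071})
#' with cost `C = 1` and `gamma = 1 / n_selected_features`, multi-class
#' handled natively by one-vs-one voting.  Any list providing `fit(x, y)`,
#' `predict(model, x)` and `decision(model, x)` satisfies the contract and
#' can be injected into [evaluate_subset()] in its place.
#'
#' @param cost regularization constant, default 1.
#' @param gamma RBF width; `NULL` (default) means `1 / ncol(x)`.
#' @param kernel kernel name passed to [e1071::svm()], default `"radial"`.
#' @return A learner contract list.
#' @export
svm_learner <- function(cost = 1, gamma = NULL, kernel = "radial") {
  list(
    fit = function(x, y) {
      g <- if (is.null(gamma)) 1 / ncol(x) else gamma
      type <- if (is.factor(y)) "C-classification" else "eps-regression"
      e1071::svm(x, y, type = type, kernel = kernel, cost = cost,
                 gamma = g, scale = FALSE)
    },
    predict = function(model, x) stats::predict(model, x),
    decision = function(model, x) {
      p <- stats::predict(model, x, decision.values = TRUE)
      attr(p, "decision.values")
    },
    # one pass for labels + decision values; evaluate_subset uses this when
    # present to avoid predicting every fold twice
    predict_full = function(model, x) {
      p <- stats::predict(model, x, decision.values = TRUE)
      list(labels = p, decision = attr(p, "decision.values"))
    }
  )
}

# per-class one-vs-rest scores from libsvm's pairwise decision values:
# each pairwise column "A/B" votes +value for A, -value for B
ovr_scores <- function(dec, classes) {
  out <- matrix(0, nrow(dec), length(classes),
                dimnames = list(NULL, classes))
  pairs <- strsplit(colnames(dec), "/", fixed = TRUE)
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    out[, a] <- out[, a] + dec[, j]
    out[, b] <- out[, b] - dec[, j]
  }
  out
}

# training-fold standardization with mean imputation, applied to both splits
fold_prepare <- function(xtr, xte) {
  mu <- colMeans(xtr, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  for (j in seq_len(ncol(xtr))) {
    miss <- is.na(xtr[, j]); if (any(miss)) xtr[miss, j] <- mu[j]
    miss <- is.na(xte[, j]); if (any(miss)) xte[miss, j] <- mu[j]
  }
  s <- apply(xtr, 2, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  m2 <- colMeans(xtr)
  xtr <- sweep(sweep(xtr, 2, m2), 2, s, "/")
  xte <- sweep(sweep(xte, 2, m2), 2, s, "/")
  list(train = xtr, test = xte)
}

#' Cross-validated evaluation of a candidate feature subset
#'
#' The wrapper fitness: the learner is trained on the selected columns of
#' each training fold (imputation and standardization fitted on that fold
#' only) and evaluated on the held-out fold.  Classification fitness is the
#' mean held-out accuracy across folds; regression fitness is the negated
#' pooled RMSE, so that every optimizer in the package maximizes.  The full
#' metric panel is computed on the pooled held-out predictions.
#'
#' @param table a [feature_table()].
#' @param cs candidate subset: integer vector of 1-based feature indices,
#'   sorted and duplicate-free.
#' @param plan a [cv_plan()].
#' @param learner a learner contract, default [svm_learner()].
#' @param metrics compute the full pooled metric panel (default).  The
#'   optimizers score millions of candidates and only need the fitness
#'   scalar, so their memoized evaluator passes `FALSE` here.
#' @return Object of class `eval_result`: `fitness` (maximization scale),
#'   `metrics` (named vector; `NULL` when `metrics = FALSE` for
#'   classification), `nof`, `task`.
#' @export
evaluate_subset <- function(table, cs, plan, learner = svm_learner(),
                            metrics = TRUE) {
  stopifnot(inherits(table, "feature_table"), inherits(plan, "cv_plan"))
  cs <- as.integer(cs)
  if (length(cs) == 0) stop("candidate subset must be non-empty")
  if (any(cs < 1 | cs > table$n_features)) {
    stop("candidate contains indices outside [1, ", table$n_features, "]")
  }
  if (is.unsorted(cs, strictly = TRUE)) {
    stop("candidate must be sorted and duplicate-free")
  }
  if (length(plan$folds) != nrow(table$x)) {
    stop("cv plan does not match the table's sample count")
  }

  x <- table$x[, cs, drop = FALSE]
  y <- table$labels
  classify <- table$task == "classification"
  n <- nrow(x)
  pred <- if (classify) factor(rep(NA, n), levels = levels(y)) else numeric(n)
  dec <- NULL
  fold_acc <- numeric(plan$k)

  for (f in seq_len(plan$k)) {
    te <- which(plan$folds == f)
    tr <- setdiff(seq_len(n), te)
    if (classify && !all(levels(y) %in% unique(as.character(y[tr])))) {
      stop("stratification error: training fold ", f, " is missing a class")
    }
    sp <- fold_prepare(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    model <- learner$fit(sp$train, y[tr])
    if (classify && !metrics) {
      p <- learner$predict(model, sp$test)
      fold_acc[f] <- mean(p == y[te])
      next
    }
    if (classify && !is.null(learner$predict_full)) {
      pf <- learner$predict_full(model, sp$test)
      p <- pf$labels
      d <- pf$decision
    } else {
      p <- learner$predict(model, sp$test)
      d <- if (classify) learner$decision(model, sp$test) else NULL
    }
    pred[te] <- p
    if (classify) {
      fold_acc[f] <- mean(p == y[te])
      if (!is.null(d)) {
        d <- as.matrix(d)
        if (is.null(dec)) dec <- matrix(NA_real_, n, ncol(d),
                                        dimnames = list(NULL, colnames(d)))
        dec[te, ] <- d
      }
    }
  }

  if (classify && !metrics) {
    return(structure(list(fitness = mean(fold_acc), metrics = NULL,
                          nof = length(cs), task = table$task),
                     class = "eval_result"))
  }
  if (classify) {
    counts <- confusion_counts(truth = y, pred = pred)
    metrics <- panel_metrics(counts)
    auc <- NA_real_
    if (!is.null(dec)) {
      sc <- ovr_scores(dec, levels(y))
      aucs <- vapply(levels(y), function(cl) {
        pos <- y == cl
        if (all(pos) || !any(pos)) return(NA_real_)
        roc_auc(sc[, cl], pos)
      }, numeric(1))
      auc <- mean(aucs, na.rm = TRUE)
    }
    metrics <- c(metrics, AUC = auc)
    fitness <- mean(fold_acc)
  } else {
    metrics <- regression_metrics(pred, y)
    fitness <- -metrics[["RMSE"]]
  }

  structure(list(fitness = fitness, metrics = metrics,
                 nof = length(cs), task = table$task),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> fitness =", format(x$fitness, digits = 4),
      " nof =", x$nof, "\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Memoizing subset evaluator
#'
#' Returns a closure `f(cs)` giving the cross-validated fitness of a
#' candidate, caching results by index set.  The WCC operators re-visit
#' subsets constantly (greedy acceptance re-scores the incumbent's
#' neighbourhood), so the cache is what keeps wrapper search affordable.
#' `attr(f, "stats")()` reports calls and cache misses; `attr(f, "full")`
#' evaluates with the complete metric panel (uncached).
#'
#' @param table a [feature_table()].
#' @param plan a [cv_plan()].
#' @param learner a learner contract.
#' @return A memoized fitness function.
#' @export
make_evaluator <- function(table, plan, learner = svm_learner()) {
  cache <- new.env(parent = emptyenv())
  calls <- 0L
  misses <- 0L
  f <- function(cs) {
    calls <<- calls + 1L
    key <- paste(cs, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    misses <<- misses + 1L
    val <- evaluate_subset(table, cs, plan, learner, metrics = FALSE)$fitness
    cache[[key]] <- val
    val
  }
  attr(f, "stats") <- function() c(calls = calls, misses = misses)
  attr(f, "full") <- function(cs) evaluate_subset(table, cs, plan, learner)
  f
}
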
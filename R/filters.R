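#' Score every feature with a classical filter statistic
#'
#' The five filter baselines.  All are univariate except the Laplacian
#' score, which uses a k-nearest-neighbour similarity graph over samples.
#'
#' \describe{
#'   \item{PC}{absolute Pearson correlation between feature and (numerically
#'     coded) label; higher is better.}
#'   \item{LA}{Laplacian score on a kNN heat-kernel graph (kernel width =
#'     median pairwise squared distance); lower is better — locality
#'     preserving features score low.}
#'   \item{EN}{information gain: label entropy minus conditional label
#'     entropy given the equal-frequency-binned feature (nats); higher is
#'     better.  This supervised form is what the filter-then-wrapper
#'     pipeline uses for its reduction step.}
#'   \item{MI}{mutual information between the binned feature and the label,
#'     in bits; higher is better.  Under identical binning EN and MI agree
#'     up to the log base.}
#'   \item{FI}{Fisher score: between-class scatter of class means over
#'     pooled within-class variance,
#'     `sum n_c (mu_c - mu)^2 / sum n_c s_c^2`; higher is better.}
#' }
#'
#' A constant feature gets the method's null value (0 for PC/EN/MI/FI, 1 for
#' LA) and is flagged in the `degenerate` field.
#'
#' @param table a [feature_table()] without missing values (canonicalize
#'   first).
#' @param method one of `"PC"`, `"LA"`, `"EN"`, `"MI"`, `"FI"`.
#' @param bins number of equal-frequency bins for EN/MI, default 10.
#' @param knn neighbourhood size for the LA graph, default 5.
#' @param kernel_width heat-kernel width for the LA graph; `NULL` (default)
#'   uses the median pairwise squared distance.
#' @return Object of class `filter_ranking`: `scores`, `direction`
#'   (`"higher_better"` or `"lower_better"`), `method`, `degenerate`
#'   (logical vector).
#' @export
filter_scores <- function(table, method = c("PC", "LA", "EN", "MI", "FI"),
                          bins = 10, knn = 5, kernel_width = NULL) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  if (anyNA(table$x)) stop("canonicalize the table before filter scoring")
  if (method %in% c("EN", "MI", "FI") && table$task != "classification") {
    stop(method, " requires classification labels")
  }
  x <- table$x
  y <- table$labels
  p <- ncol(x)
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  scores <- numeric(p)
  direction <- if (method == "LA") "lower_better" else "higher_better"

  if (method == "PC") {
    ynum <- if (is.factor(y)) as.numeric(y) else y
    for (j in seq_len(p)) {
      scores[j] <- if (const[j]) 0 else abs(stats::cor(x[, j], ynum))
    }
  } else if (method == "FI") {
    for (j in seq_len(p)) {
      scores[j] <- if (const[j]) 0 else fisher_score(x[, j], y)
    }
  } else if (method == "MI") {
    for (j in seq_len(p)) {
      scores[j] <- if (const[j]) 0 else
        mutual_information_binned(x[, j], y, bins, base = 2)
    }
  } else if (method == "EN") {
    for (j in seq_len(p)) {
      scores[j] <- if (const[j]) 0 else
        mutual_information_binned(x[, j], y, bins, base = exp(1))
    }
  } else {  # LA
    scores <- laplacian_scores(x, knn, kernel_width)
    scores[const] <- 1
  }

  structure(list(scores = scores, direction = direction, method = method,
                 degenerate = const, feature_names = table$feature_names),
            class = "filter_ranking")
}

fisher_score <- function(v, y) {
  mu <- mean(v)
  num <- 0; den <- 0
  for (lev in levels(y)) {
    vc <- v[y == lev]
    nc <- length(vc)
    num <- num + nc * (mean(vc) - mu)^2
    den <- den + nc * stats::var(vc) * (nc - 1) / nc  # population variance
  }
  # zero pooled within-class variance with real separation: perfect score
  if (den == 0) return(if (num > 0) Inf else 0)
  num / den
}

# equal-frequency binning via quantile breaks; duplicate breaks collapse so
# low-cardinality features keep their natural bins
equal_freq_bins <- function(v, bins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(factor(rep(1, length(v))))
  cut(v, breaks = br, include.lowest = TRUE)
}

mutual_information_binned <- function(v, y, bins, base = 2) {
  b <- equal_freq_bins(v, bins)
  tab <- table(b, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (pxy[i, j] > 0) {
      mi <- mi + pxy[i, j] * log(pxy[i, j] / (px[i] * py[j]), base = base)
    }
  }
  max(mi, 0)
}

# He, Cai & Niyogi style Laplacian score, lower = better locality preservation
laplacian_scores <- function(x, knn, kernel_width = NULL) {
  n <- nrow(x)
  knn <- min(knn, n - 1)
  d2 <- as.matrix(stats::dist(x))^2
  t_width <- if (is.null(kernel_width)) stats::median(d2[upper.tri(d2)]) else
    kernel_width
  if (!is.finite(t_width) || t_width <= 0) t_width <- 1
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(knn + 1)]
    s[i, nb] <- exp(-d2[i, nb] / t_width)
  }
  s <- pmax(s, t(s))  # symmetrize: an edge if either end is a neighbour
  dvec <- rowSums(s)
  lap <- diag(dvec) - s
  vapply(seq_len(ncol(x)), function(j) {
    f <- x[, j]
    ftil <- f - sum(f * dvec) / sum(dvec)
    den <- sum(ftil^2 * dvec)
    if (den == 0) return(1)
    as.numeric(crossprod(ftil, lap %*% ftil) / den)
  }, numeric(1))
}

#' Truncate a filter ranking to its k best features
#'
#' @param ranking a [filter_scores()] result.
#' @param k number of features to keep, `1 <= k <= n`.
#' @return Sorted, duplicate-free integer vector of the k best 1-based
#'   indices; ties broken by ascending index.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "filter_ranking"))
  n <- length(ranking$scores)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  key <- if (ranking$direction == "higher_better") -ranking$scores else ranking$scores
  ord <- order(key, seq_len(n))
  sort(ord[seq_len(k)])
}

#' Evaluate a filter over a grid of subset sizes
#'
#' For each k in the grid, the top-k subset is scored with
#' [evaluate_subset()]; this is the sweep used to study how a filter's
#' performance depends on the number of retained features.
#'
#' @param table a [feature_table()].
#' @param method filter name, see [filter_scores()].
#' @param k_grid integer vector of subset sizes.
#' @param plan a [cv_plan()].
#' @param learner a learner contract.
#' @param bins,knn passed to [filter_scores()].
#' @return A data frame with one row per k: `k`, `fitness` and the metric
#'   panel columns.
#' @export
filter_sweep <- function(table, method, k_grid, plan,
                         learner = svm_learner(), bins = 10, knn = 5) {
  ranking <- filter_scores(table, method, bins = bins, knn = knn)
  rows <- lapply(k_grid, function(k) {
    cs <- select_top_k(ranking, k)
    ev <- evaluate_subset(table, cs, plan, learner)
    data.frame(k = k, fitness = ev$fitness, t(ev$metrics))
  })
  do.call(rbind, rows)
}
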
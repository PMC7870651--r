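# shared fixtures: all built in code, deterministic given the stated seeds

# table whose labels equal the sign of feature 1, with a clear margin so the
# learner can realize the separation
separable_table <- function(n = 60, p = 5, seed = 11) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  sgn <- rep(c(1, -1), length.out = n)
  x[, 1] <- sgn * runif(n, 0.5, 2)
  y <- factor(ifelse(sgn > 0, "A", "B"))
  feature_table(x, y)
}

# labels independent of every feature
null_table <- function(n = 200, p = 4, seed = 5) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * p), n, p),
                factor(rep(c("A", "B"), each = n / 2)))
}

# deterministic toy fitness over subsets: rewards covering high-weight
# features, penalizes length; its global optimum is found by brute force
toy_evaluator <- function(weights, penalty = 0.05) {
  function(cs) sum(weights[cs]) - penalty * length(cs)
}

# exhaustive search over all non-empty subsets of 1:n
brute_force_best <- function(n, evaluator) {
  best <- -Inf; best_cs <- NULL
  for (mask in 1:(2^n - 1)) {
    cs <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    s <- evaluator(cs)
    if (s > best) { best <- s; best_cs <- cs }
  }
  list(score = best, cs = best_cs)
}

# pair-counting AUC oracle, independent of the rank-based implementation
auc_by_pairs <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# candidate invariant check used by the fuzz tests
expect_valid_candidate <- function(cs, n) {
  expect_true(length(cs) >= 1)
  expect_false(is.unsorted(cs, strictly = TRUE))
  expect_true(all(cs >= 1 & cs <= n))
}
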
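test_that("generated classification tables honour the requested shape and balance", {
  bench <- synth_classification(n_samples = 101, n_positive = 3,
                                n_neutral = 4, n_negative = 2,
                                n_classes = 3, effect_size = 2, seed = 9)
  tab <- bench$table
  expect_s3_class(tab, "feature_table")
  expect_equal(tab$n_features, 9)
  expect_equal(nrow(tab$x), 101)
  expect_equal(nlevels(tab$labels), 3)
  expect_lte(diff(range(table(tab$labels))), 1)  # balance within one sample
  # ground-truth sets partition 1:n
  expect_equal(sort(c(bench$truth$positive, bench$truth$neutral,
                      bench$truth$negative)), 1:9)
  # determinism
  bench2 <- synth_classification(n_samples = 101, n_positive = 3,
                                 n_neutral = 4, n_negative = 2,
                                 n_classes = 3, effect_size = 2, seed = 9)
  expect_identical(bench$table$x, bench2$table$x)
  expect_error(synth_classification(3, 1, 1, 0, n_classes = 2), "2 samples")
})

test_that("a single strong positive feature classifies almost perfectly", {
  bench <- synth_classification(n_samples = 120, n_positive = 1,
                                n_neutral = 5, n_negative = 0,
                                effect_size = 6, seed = 4)
  plan <- cv_plan(bench$table, 5, seed = 1)
  acc <- evaluate_subset(bench$table, bench$truth$positive, plan)$fitness
  expect_gte(acc, 0.95)
})

test_that("effect size monotonically improves single-feature accuracy", {
  mean_acc <- function(es) {
    accs <- vapply(1:10, function(s) {
      b <- synth_classification(n_samples = 80, n_positive = 1,
                                n_neutral = 1, n_negative = 0,
                                effect_size = es, seed = 100 + s)
      evaluate_subset(b$table, 1L, cv_plan(b$table, 5, seed = s))$fitness
    }, numeric(1))
    mean(accs)
  }
  a0 <- mean_acc(0.5); a1 <- mean_acc(1.5); a2 <- mean_acc(4)
  expect_lt(a0, a1)
  expect_lt(a1, a2)
})

test_that("zero effect size makes positives indistinguishable from neutrals", {
  bench <- synth_classification(n_samples = 300, n_positive = 2,
                                n_neutral = 2, n_negative = 0,
                                effect_size = 0, seed = 12)
  x <- bench$table$x
  y <- bench$table$labels
  for (j in 1:4) {
    p <- t.test(x[y == "C1", j], x[y == "C2", j])$p.value
    expect_gt(p, 0.001)
  }
})

test_that("redundant positives correlate with their source feature", {
  bench <- synth_classification(n_samples = 150, n_positive = 3,
                                n_neutral = 2, n_negative = 0,
                                effect_size = 2, redundancy = 1, seed = 3)
  x <- bench$table$x
  expect_gt(cor(x[, 3], x[, 1]), 0.7)  # copy tracks its source
})

test_that("regression benchmark plants a linear signal and misleading columns", {
  bench <- synth_regression(n_samples = 200, n_positive = 1, n_neutral = 3,
                            n_negative = 1, noise_sd = 0.01, seed = 6)
  tab <- bench$table
  expect_equal(tab$task, "regression")
  # near-zero noise: the single positive feature explains the target
  expect_gt(cor(tab$x[, 1], tab$labels), 0.99)
  # negative features correlate with a permuted target, not the real one
  expect_lt(abs(cor(tab$x[, 5], tab$labels)), 0.4)
  expect_equal(sort(unlist(bench$truth)), 1:5, ignore_attr = TRUE)

  # all-neutral spec: nothing predicts the target
  null_b <- synth_regression(n_samples = 100, n_positive = 0, n_neutral = 5,
                             n_negative = 0, noise_sd = 1, seed = 8)
  plan <- cv_plan(null_b$table, 5, seed = 1)
  ev <- evaluate_subset(null_b$table, 1:5, plan)
  expect_lt(abs(ev$metrics[["correlation"]]), 0.35)
})

test_that("recovery metrics count precision and recall over the positive set", {
  truth <- list(positive = 1:5, neutral = 6:40, negative = 41:50)
  expect_equal(recovery_metrics(1:5, truth),
               c(precision = 1, recall = 1))
  expect_equal(recovery_metrics(6:10, truth),
               c(precision = 0, recall = 0))
  expect_equal(recovery_metrics(1:50, truth),
               c(precision = 0.1, recall = 1))
  expect_error(recovery_metrics(1:3, list(positive = integer(0))), "empty")
})
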
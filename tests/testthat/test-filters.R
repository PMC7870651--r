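# planted table used across the filter tests: feature 1 is a copy of the
# label, the rest are noise
label_copy_table <- function(n = 200, p = 6, seed = 21) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- as.numeric(y) - 1
  feature_table(x, y)
}

test_that("perfect dependence gives PC = 1 and MI = 1 bit", {
  tab <- label_copy_table()
  pc <- filter_scores(tab, "PC")
  expect_equal(pc$scores[1], 1, tolerance = 1e-12)
  expect_equal(pc$direction, "higher_better")
  mi <- filter_scores(tab, "MI")
  expect_equal(mi$scores[1], 1, tolerance = 1e-12)  # 1 bit, balanced binary
})

test_that("Fisher score matches the hand-evaluated ratio", {
  # two classes, class means 0 and 1, within-class population variance 0.25:
  # sum n_c (mu_c - mu)^2 / sum n_c s_c^2 = (n*0.25 + n*0.25)/(n*0.25*2) = 1
  v <- c(-0.5, 0.5, -0.5, 0.5, 0.5, 1.5, 0.5, 1.5)
  y <- factor(rep(c("A", "B"), each = 4))
  tab <- feature_table(cbind(f = v, g = rnorm(8)), y)
  fi <- filter_scores(tab, "FI")
  expect_equal(fi$scores[1], 1.0, tolerance = 1e-12)
})

test_that("MI of an independent feature is near zero at large n", {
  set.seed(31)
  n <- 10000
  tab <- feature_table(cbind(a = rnorm(n), b = rnorm(n)),
                       factor(rep(c("A", "B"), each = n / 2)))
  mi <- filter_scores(tab, "MI")
  expect_lt(mi$scores[1], 0.02)   # plug-in estimator bias bound
  expect_lt(mi$scores[2], 0.02)
})

test_that("EN and MI agree up to the log base under identical binning", {
  tab <- label_copy_table(seed = 5)
  en <- filter_scores(tab, "EN")$scores
  mi <- filter_scores(tab, "MI")$scores
  expect_equal(en / log(2), mi, tolerance = 1e-10)
})

test_that("constant features receive the null score with a degeneracy flag", {
  tab <- feature_table(cbind(a = rep(2, 20), b = rnorm(20)),
                       factor(rep(c("A", "B"), 10)))
  for (m in c("PC", "EN", "MI", "FI")) {
    r <- filter_scores(tab, m)
    expect_equal(r$scores[1], 0)
    expect_true(r$degenerate[1])
  }
  la <- filter_scores(tab, "LA")
  expect_equal(la$scores[1], 1)
  expect_equal(la$direction, "lower_better")
})

test_that("PC and FI are invariant under affine rescaling; MI under monotone maps", {
  tab <- label_copy_table(seed = 13)
  tab2 <- tab
  tab2$x[, 2] <- 5 * tab2$x[, 2] - 3
  expect_equal(filter_scores(tab, "PC")$scores[2],
               filter_scores(tab2, "PC")$scores[2], tolerance = 1e-10)
  expect_equal(filter_scores(tab, "FI")$scores[2],
               filter_scores(tab2, "FI")$scores[2], tolerance = 1e-10)
  tab3 <- tab
  tab3$x[, 2] <- exp(tab3$x[, 2])   # strictly monotone, quantile bins fixed
  expect_equal(filter_scores(tab, "MI")$scores[2],
               filter_scores(tab3, "MI")$scores[2], tolerance = 1e-10)
})

test_that("select_top_k orders, breaks ties by index, respects direction, nests", {
  mk <- function(scores, direction) {
    structure(list(scores = scores, direction = direction, method = "PC",
                   degenerate = rep(FALSE, length(scores)),
                   feature_names = paste0("f", seq_along(scores))),
              class = "filter_ranking")
  }
  expect_equal(select_top_k(mk(c(0.9, 0.1, 0.5), "higher_better"), 2), c(1L, 3L))
  expect_equal(select_top_k(mk(c(0.5, 0.5, 0.5), "higher_better"), 2), c(1L, 2L))
  expect_equal(select_top_k(mk(c(0.9, 0.1, 0.5), "lower_better"), 1), 2L)
  expect_error(select_top_k(mk(c(1, 2), "higher_better"), 3), "k must lie")

  set.seed(6)
  r <- mk(sample(seq(0, 1, 0.05), 12, replace = TRUE), "higher_better")
  for (k in 1:11) {
    expect_true(all(select_top_k(r, k) %in% select_top_k(r, k + 1)))
  }
})

test_that("every filter ranks a planted strong feature highly", {
  bench <- synth_classification(n_samples = 100, n_positive = 5,
                                n_neutral = 45, n_negative = 0,
                                effect_size = 4, seed = 77)
  tab <- bench$table
  for (m in c("PC", "EN", "MI", "FI", "LA")) {
    top5 <- select_top_k(filter_scores(tab, m), 5)
    expect_gte(length(intersect(top5, bench$truth$positive)), 4)
  }
})

test_that("filter_sweep reproduces the all-features panel at k = n and nests", {
  tab <- label_copy_table(n = 80, p = 4, seed = 3)
  plan <- cv_plan(tab, 5, seed = 1)
  sw <- filter_sweep(tab, "FI", k_grid = c(1, 2, 4), plan)
  expect_equal(nrow(sw), 3)
  full <- evaluate_subset(tab, 1:4, plan)
  expect_equal(sw$fitness[3], full$fitness)
  expect_equal(sw$ACC[3], full$metrics[["ACC"]])
  # the planted label copy alone already classifies perfectly
  expect_equal(sw$fitness[1], 1.0)
})
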
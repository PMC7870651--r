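test_that("attacking overwrites k positions and can only shrink", {
  out <- attacking(c(1L, 5L, 8L), 10, k = 2, positions = c(1, 3),
                   values = c(3, 5))
  expect_equal(out, c(3L, 5L))
  # every draw hits an existing value: never longer than the input
  out2 <- attacking(c(2L, 4L, 6L), 10, k = 3, positions = c(1, 2, 3),
                    values = c(4, 6, 6))
  expect_lte(length(out2), 3)
  expect_valid_candidate(out2, 10)
})

test_that("transferring collapses onto a single donor value when forced", {
  out <- transferring(c(1L, 2L), list(9L), 10, R = 1, donors = 1, ks = 2,
                      positions = list(c(1, 2)), donor_picks = list(c(1, 1)))
  expect_equal(out, 9L)
  expect_error(transferring(c(1L, 2L), list(), 10), "non-empty")
})

test_that("transferring output values stay within input union donors", {
  set.seed(14)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    cs <- sort(sample.int(n, sample.int(min(6, n), 1)))
    top <- lapply(1:3, function(j) sort(sample.int(n, sample.int(4, 1))))
    out <- transferring(cs, top, n)
    expect_valid_candidate(out, n)
    expect_true(all(out %in% c(cs, unlist(top))))
    # donors already inside cs cannot introduce anything new
    out2 <- transferring(cs, list(cs[1], cs), n)
    expect_true(all(out2 %in% cs))
  }
})

test_that("passing is a single-edit move", {
  expect_equal(passing(c(4L, 7L), 10, pos = 2, value = 1), c(1L, 4L))
  expect_equal(passing(c(4L, 7L), 10, pos = 2, value = 4), 4L)  # collision
  set.seed(3)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    cs <- sort(sample.int(n, sample.int(min(5, n), 1)))
    out <- passing(cs, n)
    expect_valid_candidate(out, n)
    expect_lte(length(setdiff(out, cs)), 1)   # at most one inserted
    expect_lte(length(setdiff(cs, out)), 2)   # replaced + collision
  }
})

test_that("greedy acceptance requires strict improvement", {
  score_of <- c("1" = 0.80, "2" = 0.85, "3" = 0.80, "4" = 0.60)
  ev <- function(cs) unname(score_of[as.character(cs[1])])
  expect_equal(greedy_step(1L, 2L, ev)$cs, 2L)   # better: accepted
  expect_equal(greedy_step(1L, 3L, ev)$cs, 1L)   # tie: incumbent kept
  expect_equal(greedy_step(1L, 4L, ev)$cs, 1L)   # worse: rejected
})

test_that("wcc_run with a toy oracle keeps and finds the exhaustive optimum", {
  tab <- feature_table(matrix(rnorm(20 * 10), 20, 10),
                       factor(rep(c("A", "B"), 10)))
  set.seed(101)
  # mixed-sign weights: the optimum is a mid-size subset, which the
  # shrink-only operators can reach from ~0.63 n initial candidates
  w <- runif(10, -0.6, 1)
  ev <- toy_evaluator(w, penalty = 0.05)
  oracle <- brute_force_best(10, ev)
  expect_lt(length(oracle$cs), 10)

  # a seed population already containing the optimum: fitness is retained
  set.seed(5)
  seed_pop <- c(list(oracle$cs), init_population(10, ga_config(pop_size = 9)))
  run <- wcc_run(tab, seed_pop, wcc_config(pop_size = 10, iterations = 20),
                 cv_plan(tab, 4, seed = 1), evaluator = ev)
  expect_equal(run$best_score, oracle$score)
  expect_equal(run$best, oracle$cs)

  # from a random start the optimizer reaches the optimum on this toy scape
  set.seed(6)
  run2 <- wcc_run(tab, NULL, wcc_config(pop_size = 10, iterations = 40),
                  cv_plan(tab, 4, seed = 1), evaluator = ev)
  expect_equal(run2$best_score, oracle$score)
})

test_that("wcc_run respects identity edge cases and monotone trajectories", {
  tab <- separable_table(n = 40, p = 6, seed = 2)
  plan <- cv_plan(tab, 5, seed = 1)
  ev <- make_evaluator(tab, plan)
  set.seed(9)
  seed_pop <- init_population(6, ga_config(pop_size = 8))
  seed_scores <- vapply(seed_pop, ev, numeric(1))

  # zero iterations: report the best of the seed population
  r0 <- wcc_run(tab, seed_pop, wcc_config(pop_size = 8, iterations = 0),
                plan, evaluator = ev)
  expect_equal(r0$best_score, max(seed_scores))
  expect_length(r0$trajectory, 1)

  # zero match time: the population is untouched
  rm0 <- wcc_run(tab, seed_pop, wcc_config(pop_size = 8, match_time = 0,
                                           iterations = 5), plan,
                 evaluator = ev)
  expect_setequal(rm0$members, seed_pop)

  set.seed(10)
  r <- wcc_run(tab, seed_pop, wcc_config(pop_size = 8, iterations = 10),
               plan, evaluator = ev)
  expect_true(all(diff(r$trajectory) >= 0))
  for (cs in r$members) expect_valid_candidate(cs, 6)

  # a larger seed population is elitism-truncated
  rt <- wcc_run(tab, seed_pop, wcc_config(pop_size = 3, iterations = 0),
                plan, evaluator = ev)
  expect_length(rt$members, 3)
  expect_equal(rt$best_score, max(seed_scores))
})

test_that("operator fuzzing: outputs always satisfy the candidate invariants", {
  set.seed(77)
  for (i in 1:2000) {
    n <- sample(3:60, 1)
    cs <- sort(sample.int(n, sample.int(min(8, n), 1)))
    a <- sort(sample.int(n, sample.int(min(8, n), 1)))
    expect_valid_candidate(mutate_candidate(cs, n), n)
    kids <- crossover_candidates(cs, a, n)
    expect_valid_candidate(kids[[1]], n)
    expect_valid_candidate(kids[[2]], n)
    out <- attacking(cs, n)
    expect_valid_candidate(out, n)
    expect_lte(length(out), length(cs))
  }
})
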
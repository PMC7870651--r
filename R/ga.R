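#' @title Variable-length candidate subsets and the genetic algorithm
#' @description The first search stage: a GA over variable-length,
#'   duplicate-free, sorted vectors of feature indices.  Operators follow
#'   value semantics (inputs are never modified) and every output is
#'   re-canonicalized: duplicates removed, indices sorted, an empty result
#'   replaced by one fresh uniform draw.
#' @name ga_engine
NULL

# canonical form of a candidate: sorted, unique, never empty
canonical_candidate <- function(values, n) {
  v <- sort(unique(as.integer(values)))
  if (length(v) == 0) v <- sample.int(n, 1)
  v
}

rand_index <- function(n) sample.int(n, 1)

#' Genetic-algorithm configuration
#'
#' Defaults follow the published configuration of the method: population
#' 100, mutation and crossover rates 30%, termination when the best fitness
#' has not changed for 10 consecutive generations.
#'
#' @param pop_size population size, default 100.
#' @param mutation_rate fraction of the population mutated per generation,
#'   default 0.30.
#' @param crossover_rate fraction of the population entering crossover per
#'   generation (pairs = `crossover_rate * pop_size / 2`), default 0.30.
#' @param init_length number of index draws per initial candidate (with
#'   replacement, before deduplication); `NULL` = the feature count `n`,
#'   which leaves initial candidates at roughly `0.63 n` unique features.
#'   Because every operator can only shrink a candidate, this bounds the
#'   largest subset the search can ever return.
#' @param stagnation_window generations of unchanged best fitness that stop
#'   the run, default 10.
#' @param max_generations hard cap, default 500.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 100, mutation_rate = 0.3,
                      crossover_rate = 0.3, init_length = NULL,
                      stagnation_window = 10, max_generations = 500) {
  if (pop_size < 2) stop("pop_size must be at least 2")
  if (mutation_rate < 0 || mutation_rate > 1 ||
      crossover_rate < 0 || crossover_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (!is.null(init_length) && init_length < 1) {
    stop("init_length must be positive")
  }
  if (stagnation_window < 1) stop("stagnation_window must be at least 1")
  structure(list(pop_size = as.integer(pop_size),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 init_length = init_length,
                 stagnation_window = as.integer(stagnation_window),
                 max_generations = as.integer(max_generations)),
            class = "ga_config")
}

# Draws equal the feature count: duplicates are then frequent, so initial
# candidates have varying (~0.63 n) lengths, and -- since every operator can
# only shrink a candidate -- any subset size up to the largest initial
# length stays reachable.
auto_init_length <- function(n) max(2, n)

#' Initialize a random population of candidate subsets
#'
#' Each candidate is built by drawing `init_length` indices uniformly from
#' `[1, n]` with replacement, then deduplicating and sorting — so initial
#' lengths may vary even though every candidate starts from the same number
#' of draws.
#'
#' @param n total number of features.
#' @param cfg a [ga_config()] (only `pop_size` and `init_length` are used).
#' @return List of `pop_size` candidate index vectors.
#' @export
init_population <- function(n, cfg = ga_config()) {
  len <- if (is.null(cfg$init_length)) auto_init_length(n) else
    min(cfg$init_length, n * 10L)  # draws with replacement; cap for sanity
  lapply(seq_len(cfg$pop_size), function(i) {
    canonical_candidate(sample.int(n, len, replace = TRUE), n)
  })
}

#' Mutation operator
#'
#' Replaces the value at one randomly chosen position by a uniform draw from
#' `[1, n]`, then re-canonicalizes; the candidate shrinks by one exactly
#' when the drawn value is already present.
#'
#' @param cs candidate index vector.
#' @param n total number of features.
#' @param pos,value optional forced draws (1-based position in `cs` and the
#'   replacement feature index); used for reproducing specific transitions.
#' @return The mutated candidate.
#' @export
mutate_candidate <- function(cs, n, pos = NULL, value = NULL) {
  if (is.null(pos)) pos <- rand_index(length(cs))
  if (is.null(value)) value <- rand_index(n)
  cs[pos] <- value
  canonical_candidate(cs, n)
}

#' Range crossover operator
#'
#' Draws one contiguous window of identical length `L` in each parent
#' (`1 <= L <= min(length(a), length(b))`), swaps the window contents, and
#' re-canonicalizes both children, which may therefore be shorter than their
#' parents.
#'
#' @param a,b parent candidates.
#' @param n total number of features.
#' @param L,start_a,start_b optional forced draws: window length and window
#'   start positions in each parent.
#' @return List of the two children.
#' @export
crossover_candidates <- function(a, b, n, L = NULL, start_a = NULL,
                                 start_b = NULL) {
  lmax <- min(length(a), length(b))
  if (is.null(L)) L <- rand_index(lmax)
  if (is.null(start_a)) start_a <- rand_index(length(a) - L + 1)
  if (is.null(start_b)) start_b <- rand_index(length(b) - L + 1)
  ia <- start_a:(start_a + L - 1)
  ib <- start_b:(start_b + L - 1)
  tmp <- a[ia]
  a[ia] <- b[ib]
  b[ib] <- tmp
  list(canonical_candidate(a, n), canonical_candidate(b, n))
}

# deterministic elitism order: fitness desc, then shorter candidate, then
# lexicographic on the index vectors
elitism_order <- function(members, scores) {
  lens <- lengths(members)
  lex <- vapply(members, function(m) paste(sprintf("%09d", m), collapse = ""),
                character(1))
  order(-scores, lens, lex)
}

#' Elitism selection
#'
#' Keeps the `out_size` highest-fitness members; ties prefer the shorter
#' candidate, then lexicographic index order, so selection is fully
#' deterministic.
#'
#' @param members list of candidates.
#' @param scores fitness vector aligned with `members`.
#' @param out_size number of members to keep.
#' @return List with elements `members` and `scores`, both reordered and
#'   truncated.
#' @export
elitism_select <- function(members, scores, out_size) {
  if (length(members) != length(scores)) stop("scores misaligned with members")
  if (out_size > length(members)) {
    stop("out_size exceeds the candidate pool")
  }
  keep <- elitism_order(members, scores)[seq_len(out_size)]
  list(members = members[keep], scores = scores[keep])
}

#' Run the genetic algorithm stage
#'
#' Loop of score / crossover / mutate / elitism-select.  Each generation,
#' `crossover_rate * pop_size / 2` random parent pairs produce two children
#' each and `mutation_rate * pop_size` random members produce one mutant
#' each; children and mutants join the parents in one pool from which
#' elitism keeps the best `pop_size`.  The run stops when the best fitness
#' has stayed constant (within 1e-12) for `stagnation_window` consecutive
#' generations, or at `max_generations`.
#'
#' @param table a [feature_table()].
#' @param cfg a [ga_config()].
#' @param plan a [cv_plan()].
#' @param evaluator optional memoized evaluator from [make_evaluator()];
#'   sharing one lets the WCC stage reuse the GA's score cache.
#' @param learner a learner contract (ignored when `evaluator` is given).
#' @return List: `members`, `scores` (final population, elitism-ordered),
#'   `best`, `best_score`, `trajectory` (best fitness per generation,
#'   including the initial population), `generations`.
#' @export
ga_run <- function(table, cfg = ga_config(), plan, evaluator = NULL,
                   learner = svm_learner()) {
  stopifnot(inherits(table, "feature_table"))
  n <- table$n_features
  if (is.null(evaluator)) evaluator <- make_evaluator(table, plan, learner)

  members <- init_population(n, cfg)
  scores <- vapply(members, evaluator, numeric(1))
  sel <- elitism_select(members, scores, cfg$pop_size)
  members <- sel$members; scores <- sel$scores
  trajectory <- scores[1]
  streak <- 0L
  gen <- 1L
  tol <- 1e-12

  while (gen < cfg$max_generations && streak < cfg$stagnation_window) {
    gen <- gen + 1L
    offspring <- list()
    n_pairs <- round(cfg$crossover_rate * cfg$pop_size / 2)
    for (i in seq_len(n_pairs)) {
      pr <- sample.int(cfg$pop_size, 2)
      kids <- crossover_candidates(members[[pr[1]]], members[[pr[2]]], n)
      offspring <- c(offspring, kids)
    }
    n_mut <- round(cfg$mutation_rate * cfg$pop_size)
    if (n_mut > 0) {
      who <- sample.int(cfg$pop_size, n_mut)
      offspring <- c(offspring,
                     lapply(members[who], mutate_candidate, n = n))
    }
    pool <- c(members, offspring)
    pool_scores <- c(scores, vapply(offspring, evaluator, numeric(1)))
    sel <- elitism_select(pool, pool_scores, cfg$pop_size)
    members <- sel$members; scores <- sel$scores
    best_now <- scores[1]
    streak <- if (abs(best_now - trajectory[length(trajectory)]) <= tol)
      streak + 1L else 0L
    trajectory <- c(trajectory, best_now)
  }

  list(members = members, scores = scores,
       best = members[[1]], best_score = scores[1],
       trajectory = trajectory, generations = gen)
}
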
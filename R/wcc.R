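#' WCC configuration
#'
#' World Competitive Contests stage.  Published defaults: population 20 when
#' run standalone (the GA hand-off population replaces it in the two-stage
#' method), match time 2 standalone and 1 inside the two-stage method, a
#' fixed iteration budget (100 in the reference experiments), and 5
#' top-ranked candidates feeding the transferring operator.
#'
#' @param pop_size population size for standalone runs, default 20.
#' @param match_time attempts to change each candidate per iteration,
#'   default 2.
#' @param iterations fixed iteration budget, default 100.
#' @param top_count number of highest-score candidates that donate values in
#'   transferring, default 5.
#' @return A `wcc_config` list.
#' @export
wcc_config <- function(pop_size = 20, match_time = 2, iterations = 100,
                       top_count = 5) {
  if (pop_size < 1) stop("pop_size must be positive")
  if (match_time < 0) stop("match_time must be non-negative")
  if (iterations < 0) stop("iterations must be non-negative")
  if (top_count < 1) stop("top_count must be positive")
  structure(list(pop_size = as.integer(pop_size),
                 match_time = as.integer(match_time),
                 iterations = as.integer(iterations),
                 top_count = as.integer(top_count)),
            class = "wcc_config")
}

#' Attacking operator
#'
#' Draws `k` uniform in `[1, length(cs)]`, then `k` times overwrites a
#' random position with a uniform feature index from `[1, n]`; the result is
#' deduplicated and sorted, so the candidate may shrink but never grow.
#'
#' @param cs candidate index vector.
#' @param n total number of features.
#' @param k,positions,values optional forced draws: number of overwrites,
#'   the positions hit, and the replacement values.
#' @return The attacked candidate.
#' @export
attacking <- function(cs, n, k = NULL, positions = NULL, values = NULL) {
  len <- length(cs)
  if (is.null(k)) k <- rand_index(len)
  if (is.null(positions)) positions <- sample.int(len, k, replace = TRUE)
  if (is.null(values)) values <- sample.int(n, k, replace = TRUE)
  for (i in seq_len(k)) cs[positions[i]] <- values[i]
  canonical_candidate(cs, n)
}

#' Transferring operator
#'
#' Imports values from the current top candidates: `R` uniform in
#' `[1, length(top)]` times, a donor is chosen uniformly and `k` uniform in
#' `[1, length(cs)]` of the candidate's positions are overwritten with
#' uniformly chosen donor values.  Every output value therefore belongs to
#' the original candidate or to one of the donors.
#'
#' @param cs candidate index vector.
#' @param top non-empty list of donor candidates (highest-score members).
#' @param n total number of features.
#' @param R,donors,ks,positions,donor_picks optional forced draws: the
#'   number of donor rounds, donor index per round, overwrites per round,
#'   and per-round lists of positions in `cs` and of positions in the donor.
#' @return The modified candidate.
#' @export
transferring <- function(cs, top, n, R = NULL, donors = NULL, ks = NULL,
                         positions = NULL, donor_picks = NULL) {
  if (length(top) == 0) stop("transferring requires a non-empty top list")
  if (is.null(R)) R <- rand_index(length(top))
  len <- length(cs)
  for (j in seq_len(R)) {
    donor <- if (is.null(donors)) top[[rand_index(length(top))]] else
      top[[donors[j]]]
    k <- if (is.null(ks)) rand_index(len) else ks[j]
    for (i in seq_len(k)) {
      r <- if (is.null(positions)) rand_index(len) else positions[[j]][i]
      pick <- if (is.null(donor_picks)) rand_index(length(donor)) else
        donor_picks[[j]][i]
      cs[r] <- donor[pick]
    }
  }
  canonical_candidate(cs, n)
}

#' Passing operator
#'
#' The low-disturbance move: exactly one randomly chosen position is
#' overwritten by a uniform draw from `[1, n]`, then the candidate is
#' deduplicated and sorted.  At most one value is removed and one inserted.
#'
#' @param cs candidate index vector.
#' @param n total number of features.
#' @param pos,value optional forced draws.
#' @return The modified candidate.
#' @export
passing <- function(cs, n, pos = NULL, value = NULL) {
  mutate_candidate(cs, n, pos = pos, value = value)
}

#' Greedy acceptance step
#'
#' A proposal replaces the incumbent only if its fitness strictly exceeds
#' the incumbent's; ties keep the incumbent.  This is what makes every WCC
#' fitness trajectory non-decreasing.
#'
#' @param cs incumbent candidate.
#' @param proposal proposed candidate.
#' @param evaluator fitness function (memoized, see [make_evaluator()]).
#' @return List `(cs, score)` of the surviving candidate.
#' @export
greedy_step <- function(cs, proposal, evaluator) {
  s_inc <- evaluator(cs)
  s_prop <- evaluator(proposal)
  if (s_prop > s_inc) list(cs = proposal, score = s_prop)
  else list(cs = cs, score = s_inc)
}

#' Run the WCC stage
#'
#' Takes a scored seed population (normally the GA's terminal population;
#' pass `NULL` for a standalone run with random initialization) and applies,
#' for a fixed number of iterations, `match_time` change attempts to every
#' member.  One attempt applies attacking, transferring and passing in
#' sequence, each followed by greedy accept-if-improved.  The list of
#' `top_count` donors is refreshed at the start of every iteration.
#'
#' @param table a [feature_table()].
#' @param seed_pop list of candidate index vectors, or `NULL` to initialize
#'   `pop_size` random candidates.
#' @param cfg a [wcc_config()].  A seed population larger than `pop_size`
#'   is elitism-truncated (set `pop_size` to the hand-off size to keep it
#'   whole, as the two-stage pipeline does).
#' @param plan a [cv_plan()].
#' @param evaluator optional memoized evaluator (shares the GA cache in the
#'   two-stage pipeline).
#' @param learner a learner contract (ignored when `evaluator` is given).
#' @return List: `members`, `scores`, `best`, `best_score`, `trajectory`
#'   (global best per iteration, first entry = seed best), `evals`.
#' @export
wcc_run <- function(table, seed_pop = NULL, cfg = wcc_config(), plan,
                    evaluator = NULL, learner = svm_learner()) {
  stopifnot(inherits(table, "feature_table"))
  n <- table$n_features
  if (is.null(evaluator)) evaluator <- make_evaluator(table, plan, learner)
  if (is.null(seed_pop)) {
    seed_pop <- init_population(n, ga_config(pop_size = max(cfg$pop_size, 2)))
    seed_pop <- seed_pop[seq_len(cfg$pop_size)]
  }
  if (length(seed_pop) == 0) stop("seed population must be non-empty")

  members <- seed_pop
  scores <- vapply(members, evaluator, numeric(1))
  if (length(members) > cfg$pop_size) {
    sel <- elitism_select(members, scores, cfg$pop_size)
    members <- sel$members; scores <- sel$scores
  }
  m <- length(members)
  trajectory <- max(scores)

  for (iter in seq_len(cfg$iterations)) {
    top_idx <- elitism_order(members, scores)[seq_len(min(cfg$top_count, m))]
    top <- members[top_idx]
    for (i in seq_len(m)) {
      cur <- members[[i]]; cur_s <- scores[i]
      for (t in seq_len(cfg$match_time)) {
        st <- greedy_step(cur, attacking(cur, n), evaluator)
        cur <- st$cs
        st <- greedy_step(cur, transferring(cur, top, n), evaluator)
        cur <- st$cs
        st <- greedy_step(cur, passing(cur, n), evaluator)
        cur <- st$cs; cur_s <- st$score
      }
      members[[i]] <- cur
      scores[i] <- evaluator(cur)
    }
    trajectory <- c(trajectory, max(scores))
  }

  ord <- elitism_order(members, scores)
  st <- attr(evaluator, "stats")
  list(members = members[ord], scores = scores[ord],
       best = members[[ord[1]]], best_score = scores[ord[1]],
       trajectory = trajectory,
       evals = if (is.null(st)) NULL else st())
}
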
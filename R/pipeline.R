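#' Select features by wrapper, two-stage, or filter methods
#'
#' The package's main fitting function.  Methods:
#' \describe{
#'   \item{`"ga_wcc"`}{the two-stage wrapper: a variable-length GA runs to
#'     stagnation, and its whole terminal population seeds the WCC
#'     optimizer (match time 1), which returns the best candidate found.}
#'   \item{`"wcc"`}{standalone WCC: random initial population (default 20),
#'     match time 2.}
#'   \item{`"ga"`}{standalone GA, best of the terminal population.}
#'   \item{`"en_wcc"`}{filter-then-wrapper: the information-gain filter
#'     keeps the `filter_k` best features, and standalone WCC searches
#'     inside that reduced space; reported indices are mapped back to the
#'     original coordinates.}
#'   \item{`"pc"`, `"la"`, `"en"`, `"mi"`, `"fi"`}{pure filter baselines:
#'     top-`filter_k` by the corresponding score.}
#' }
#'
#' All randomness (folds, initialization, operators) flows from `seed`, so a
#' fit is a pure function of `(data, arguments)`.
#'
#' @param x a [feature_table()], a numeric matrix/data frame of features, or
#'   a formula.
#' @param ... method arguments (below), or `data` for the formula interface.
#' @param y labels, when `x` is a matrix or data frame.
#' @param method one of the method names above (case-insensitive).
#' @param ga a [ga_config()].
#' @param wcc a [wcc_config()], or `NULL` for the method-appropriate
#'   default (match time 1 inside `"ga_wcc"`, 2 elsewhere).
#' @param filter_k subset size for filter methods and the reduction size for
#'   `"en_wcc"`; default `min(n, 20)`.
#' @param folds number of cross-validation folds, default 5.
#' @param plan optional pre-built [cv_plan()]; overrides `folds`.  Fixing
#'   one plan across runs makes every fitness value comparable (the same
#'   deterministic objective), while `seed` then varies only the search.
#' @param seed integer seed, default 1.
#' @param learner a learner contract, default [svm_learner()].
#' @param bins discretization bins for the entropy / mutual-information
#'   filters, default 10.
#' @return An object of class `fs_fit`; see [print.fs_fit()],
#'   [summary.fs_fit()], [coef.fs_fit()], [plot.fs_fit()],
#'   [predict.fs_fit()].
#' @examples
#' bench <- synth_classification(n_samples = 60, n_positive = 2,
#'                               n_neutral = 6, n_negative = 0,
#'                               effect_size = 3, seed = 7)
#' fit <- feature_select(bench$table, method = "ga_wcc",
#'                       ga = ga_config(pop_size = 20),
#'                       wcc = wcc_config(iterations = 5), seed = 7)
#' fit
#' coef(fit)
#' @export
feature_select <- function(x, ...) UseMethod("feature_select")

#' @rdname feature_select
#' @export
feature_select.default <- function(x, y, ...) {
  feature_select(feature_table(x, y), ...)
}

#' @rdname feature_select
#' @param formula a formula `label ~ .` naming the label column.
#' @param data data frame holding features and the label.
#' @export
feature_select.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  feats <- mf[, -1, drop = FALSE]
  feature_select(feature_table(as.matrix(feats), y), ...)
}

#' @rdname feature_select
#' @export
feature_select.feature_table <- function(x, method = "ga_wcc",
                                         ga = ga_config(), wcc = NULL,
                                         filter_k = NULL, folds = 5,
                                         plan = NULL, seed = 1,
                                         learner = svm_learner(),
                                         bins = 10, ...) {
  table <- x
  method <- tolower(method)
  valid <- c("ga_wcc", "en_wcc", "ga", "wcc", "pc", "la", "en", "mi", "fi")
  if (!method %in% valid) {
    stop("unknown method '", method, "'; expected one of ",
         paste(valid, collapse = ", "))
  }
  n <- table$n_features
  if (is.null(filter_k)) filter_k <- min(n, 20L)
  if (filter_k > n) stop("filter_k exceeds the number of features")

  if (is.null(plan)) plan <- cv_plan(table, k = folds, seed = seed)
  stopifnot(inherits(plan, "cv_plan"))
  set.seed(seed)
  evaluator <- make_evaluator(table, plan, learner)

  trajectory <- numeric(0)
  generations <- NA_integer_

  if (method %in% c("pc", "la", "en", "mi", "fi")) {
    ranking <- filter_scores(table, toupper(method), bins = bins)
    selected <- select_top_k(ranking, filter_k)
    trajectory <- evaluator(selected)
  } else if (method == "ga") {
    run <- ga_run(table, ga, plan, evaluator = evaluator)
    selected <- run$best
    trajectory <- run$trajectory
    generations <- run$generations
  } else if (method == "wcc") {
    if (is.null(wcc)) wcc <- wcc_config()
    run <- wcc_run(table, NULL, wcc, plan, evaluator = evaluator)
    selected <- run$best
    trajectory <- run$trajectory
  } else if (method == "ga_wcc") {
    if (is.null(wcc)) wcc <- wcc_config(match_time = 1)
    ga_res <- ga_run(table, ga, plan, evaluator = evaluator)
    wcc$pop_size <- length(ga_res$members)  # keep the whole hand-off
    run <- wcc_run(table, ga_res$members, wcc, plan, evaluator = evaluator)
    selected <- run$best
    trajectory <- c(ga_res$trajectory, run$trajectory[-1])
    generations <- ga_res$generations
  } else {  # en_wcc
    if (is.null(wcc)) wcc <- wcc_config(match_time = 2, pop_size = 20)
    ranking <- filter_scores(table, "EN", bins = bins)
    kept <- select_top_k(ranking, filter_k)
    sub <- feature_table(table$x[, kept, drop = FALSE], table$labels,
                         task = table$task)
    sub_eval <- make_evaluator(sub, plan, learner)
    run <- wcc_run(sub, NULL, wcc, plan, evaluator = sub_eval)
    selected <- sort(kept[run$best])  # back to original coordinates
    trajectory <- run$trajectory
  }

  panel <- attr(evaluator, "full")(selected)

  structure(list(
    method = method,
    selected = as.integer(selected),
    feature_names = table$feature_names[selected],
    nof = length(selected),
    fitness = panel$fitness,
    panel = panel,
    trajectory = trajectory,
    generations = generations,
    task = table$task,
    n_features = n,
    n_samples = nrow(table$x),
    folds = as.integer(plan$k),
    seed = as.integer(seed),
    config = list(ga = unclass(ga), wcc = if (is.null(wcc)) NULL else
      unclass(wcc), filter_k = as.integer(filter_k), bins = as.integer(bins)),
    evals = unname(attr(evaluator, "stats")()["misses"]),
    call = match.call()
  ), class = "fs_fit")
}

#' Baseline: score the full feature set
#'
#' The no-selection reference: [evaluate_subset()] on all features.
#'
#' @param table a [feature_table()].
#' @param plan a [cv_plan()].
#' @param learner a learner contract.
#' @return An `eval_result`.
#' @export
run_baseline_svm <- function(table, plan, learner = svm_learner()) {
  evaluate_subset(table, seq_len(table$n_features), plan, learner)
}

#' Compare two sets of execution outcomes
#'
#' Two-sample test on terminal fitness values from repeated executions,
#' Welch's t-test by default (equivalent to one-way ANOVA for two groups
#' with unequal variances) or the Wilcoxon rank-sum test.  When both groups
#' are constant, equal means give p = 1 (no evidence of difference) and
#' unequal means p = 0 by convention.
#'
#' @param runs_a,runs_b numeric vectors, each of length >= 2.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return List `(p_value, statistic, test)`.
#' @export
compare_executions <- function(runs_a, runs_b, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (length(runs_a) < 2 || length(runs_b) < 2) {
    stop("need at least 2 executions per group")
  }
  if (stats::sd(runs_a) == 0 && stats::sd(runs_b) == 0) {
    same <- isTRUE(all.equal(mean(runs_a), mean(runs_b)))
    return(list(p_value = if (same) 1 else 0,
                statistic = if (same) 0 else Inf, test = test))
  }
  if (test == "welch") {
    ht <- stats::t.test(runs_a, runs_b)
  } else {
    ht <- stats::wilcox.test(runs_a, runs_b, exact = FALSE)
  }
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       test = test)
}

#' Summarize repeated execution outcomes
#'
#' Mean, sample standard deviation and a t-based confidence interval of the
#' terminal metric over executions.
#'
#' @param runs numeric vector of length >= 2.
#' @param confidence confidence level, default 0.95.
#' @return List `(mean, std, ci_low, ci_high, n, confidence)`.
#' @export
summarize_executions <- function(runs, confidence = 0.95) {
  n <- length(runs)
  if (n < 2) stop("need at least 2 executions to summarize")
  m <- mean(runs)
  s <- stats::sd(runs)
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * s / sqrt(n)
  list(mean = m, std = s, ci_low = m - half, ci_high = m + half,
       n = n, confidence = confidence)
}

#' Multi-execution comparison experiment
#'
#' Runs each method `executions` times with distinct derived seeds on the
#' same table and cross-validation protocol, collects terminal fitness
#' values, summarizes them and tests every method against the first one
#' (the test base).  The reported `best` fit per method is the
#' best-of-executions, with the full fitness distribution retained.
#'
#' @param table a [feature_table()].
#' @param methods character vector of method names, first = test base.
#' @param executions runs per method (published protocol: 50 for the
#'   classification comparisons, at least 30 for regression).
#' @param seed master seed; per-execution seeds are derived from it.
#' @param confidence level for the summary intervals, default 0.95.
#' @param test `"welch"` or `"wilcoxon"`, see [compare_executions()].
#' @param ... further arguments passed to [feature_select()].
#' @return Object of class `fs_experiment`: `per_execution` (matrix,
#'   executions x methods), `summaries`, `comparisons`, `best_fits`.
#' @export
fs_experiment <- function(table, methods = c("ga_wcc", "wcc", "ga"),
                          executions = 50, seed = 1, confidence = 0.95,
                          test = "welch", ...) {
  stopifnot(inherits(table, "feature_table"), executions >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, executions)
  per_exec <- matrix(NA_real_, executions, length(methods),
                     dimnames = list(NULL, methods))
  best_fits <- vector("list", length(methods))
  names(best_fits) <- methods
  for (j in seq_along(methods)) {
    fits <- lapply(seeds, function(s) {
      feature_select(table, method = methods[j], seed = s, ...)
    })
    per_exec[, j] <- vapply(fits, `[[`, numeric(1), "fitness")
    best_fits[[j]] <- fits[[which.max(per_exec[, j])]]
  }
  summaries <- if (executions >= 2) {
    lapply(seq_along(methods), function(j)
      summarize_executions(per_exec[, j], confidence))
  } else NULL
  if (!is.null(summaries)) names(summaries) <- methods
  comparisons <- if (executions >= 2 && length(methods) > 1) {
    out <- lapply(seq_along(methods)[-1], function(j)
      compare_executions(per_exec[, 1], per_exec[, j], test))
    names(out) <- methods[-1]
    out
  } else NULL
  structure(list(methods = methods, executions = executions,
                 per_execution = per_exec, summaries = summaries,
                 comparisons = comparisons, best_fits = best_fits,
                 seed = as.integer(seed), test = test),
            class = "fs_experiment")
}

#' @export
print.fs_experiment <- function(x, ...) {
  cat("<fs_experiment> ", x$executions, " executions x ",
      length(x$methods), " methods (base: ", x$methods[1], ")\n", sep = "")
  for (m in x$methods) {
    s <- x$summaries[[m]]
    if (is.null(s)) next
    line <- sprintf("  %-8s mean %.4f  std %.4f  CI [%.4f, %.4f]",
                    m, s$mean, s$std, s$ci_low, s$ci_high)
    cmp <- x$comparisons[[m]]
    if (!is.null(cmp)) line <- paste0(line, sprintf("  p=%.3g", cmp$p_value))
    cat(line, "\n")
  }
  invisible(x)
}
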
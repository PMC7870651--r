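#' Print a feature-selection fit
#'
#' @param x an `fs_fit` from [feature_select()].
#' @param ... ignored.
#' @export
print.fs_fit <- function(x, ...) {
  cat("<fs_fit> method =", toupper(x$method),
      " task =", x$task, "\n")
  cat("  selected", x$nof, "of", x$n_features, "features\n")
  if (x$task == "classification") {
    cat("  CV accuracy:", format(x$panel$metrics[["ACC"]], digits = 4), "\n")
  } else {
    cat("  CV RMSE:", format(x$panel$metrics[["RMSE"]], digits = 4),
        " correlation:", format(x$panel$metrics[["correlation"]], digits = 4),
        "\n")
  }
  invisible(x)
}

#' Summarize a feature-selection fit
#'
#' @param object an `fs_fit`.
#' @param ... ignored.
#' @export
summary.fs_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.fs_fit")
}

#' @export
print.summary.fs_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  features:", paste(f$feature_names, collapse = ", "), "\n")
  cat("  indices: ", paste(f$selected, collapse = ", "), "\n")
  cat("  metric panel:\n")
  print(round(f$panel$metrics, 4))
  if (length(f$trajectory) > 1) {
    cat("  trajectory:", length(f$trajectory), "points, ",
        format(f$trajectory[1], digits = 4), "->",
        format(f$trajectory[length(f$trajectory)], digits = 4), "\n")
  }
  cat("  subset evaluations:", f$evals, " seed:", f$seed, "\n")
  invisible(x)
}

#' Selected feature indices of a fit
#'
#' @param object an `fs_fit`.
#' @param names return feature names instead of 1-based indices.
#' @param ... ignored.
#' @return Integer vector of selected indices (or character names).
#' @export
coef.fs_fit <- function(object, names = FALSE, ...) {
  if (names) object$feature_names else object$selected
}

#' Plot the best-fitness trajectory of a fit
#'
#' @param x an `fs_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fs_fit <- function(x, ...) {
  if (length(x$trajectory) < 1) stop("fit has no trajectory to plot")
  graphics::plot(seq_along(x$trajectory), x$trajectory, type = "s",
                 xlab = "iteration", ylab = "best fitness",
                 main = paste(toupper(x$method), "convergence"), ...)
  invisible(x)
}

#' Predict from a feature-selection fit
#'
#' Refits the learner on the training table restricted to the selected
#' features (imputation and standardization fitted on the whole training
#' table) and predicts the new samples.
#'
#' @param object an `fs_fit`.
#' @param table the training [feature_table()] the fit was produced from.
#' @param newdata numeric matrix or data frame with the same feature
#'   columns as the training table.
#' @param learner a learner contract, default [svm_learner()].
#' @param ... ignored.
#' @return Predicted labels (factor) or numeric targets.
#' @export
predict.fs_fit <- function(object, table, newdata,
                           learner = svm_learner(), ...) {
  stopifnot(inherits(table, "feature_table"))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != table$n_features) {
    stop("newdata must have the training table's ", table$n_features,
         " feature columns")
  }
  sp <- fold_prepare(table$x[, object$selected, drop = FALSE],
                     newdata[, object$selected, drop = FALSE])
  model <- learner$fit(sp$train, table$labels)
  learner$predict(model, sp$test)
}

#' Write a feature-selection report
#'
#' Emits a machine-readable JSON report (selected feature names, 1-based
#' indices, metric panel, per-iteration best-fitness trajectory, seed and a
#' config echo) plus a flat TSV summary next to it.
#'
#' @param fit an `fs_fit`.
#' @param path output path for the JSON report; the TSV summary is written
#'   to the same path with extension `.tsv`.
#' @return `path`, invisibly.
#' @seealso [read_fs_report()]
#' @export
write_fs_report <- function(fit, path) {
  stopifnot(inherits(fit, "fs_fit"))
  if (length(fit$trajectory) < 1) {
    stop("refusing to write a report for a run that never evaluated")
  }
  rep <- list(
    method = fit$method,
    task = fit$task,
    selected_indices = fit$selected,
    selected_names = fit$feature_names,
    nof = fit$nof,
    fitness = fit$fitness,
    metrics = as.list(fit$panel$metrics),
    trajectory = fit$trajectory,
    seed = fit$seed,
    folds = fit$folds,
    n_features = fit$n_features,
    n_samples = fit$n_samples,
    config = fit$config
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tsv <- sub("\\.json$", "", path)
  tsv <- paste0(tsv, ".tsv")
  flat <- data.frame(
    key = c("method", "task", "nof", "fitness",
            names(fit$panel$metrics), "seed", "selected"),
    value = c(fit$method, fit$task, fit$nof, fit$fitness,
              unname(fit$panel$metrics), fit$seed,
              paste(fit$selected, collapse = ",")),
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a feature-selection report
#'
#' @param path path to a JSON report written by [write_fs_report()].
#' @return The parsed report list; `selected_indices` is an integer vector.
#' @export
read_fs_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$selected_indices <- as.integer(rep$selected_indices)
  rep
}
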
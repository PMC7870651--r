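#' Construct a feature table
#'
#' A `feature_table` is the dataset container every selector in this package
#' operates on: a numeric samples-by-features matrix plus a per-sample label
#' (a factor for classification, a numeric target for regression).  Missing
#' measurements are kept as `NA` until [canonicalize()] (or per-fold handling
#' inside [evaluate_subset()]) resolves them.
#'
#' @param x numeric matrix or data frame of features, samples in rows.
#' @param labels per-sample labels: factor/character for classification,
#'   numeric for regression.  Length must equal `nrow(x)`.
#' @param task `"auto"` (default), `"classification"` or `"regression"`.
#'   With `"auto"`, non-numeric labels give classification and numeric labels
#'   give regression.
#' @param feature_names optional character vector of unique column names;
#'   defaults to the column names of `x` or `f1, f2, ...`.
#'
#' @return An object of class `feature_table` with elements `x` (numeric
#'   matrix), `labels`, `task`, `n_features`, `feature_names` and
#'   `canonicalized` (logical).
#' @seealso [read_feature_table()], [canonicalize()]
#' @export
feature_table <- function(x, labels,
                          task = c("auto", "classification", "regression"),
                          feature_names = NULL) {
  task <- match.arg(task)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(labels)) {
    stop("row count of the feature matrix (", nrow(x),
         ") must equal the number of labels (", length(labels), ")")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(x)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(x)))
  }
  if (length(feature_names) != ncol(x)) {
    stop("feature_names must have one entry per feature column")
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique")
  }
  colnames(x) <- feature_names

  if (task == "auto") {
    task <- if (is.numeric(labels)) "regression" else "classification"
  }
  if (task == "classification") {
    labels <- factor(labels)
    if (nlevels(labels) < 2) {
      stop("classification labels must take at least 2 distinct values")
    }
  } else {
    labels <- as.numeric(labels)
    if (anyNA(labels)) stop("regression labels must be numeric and complete")
  }

  structure(
    list(x = x, labels = labels, task = task,
         n_features = ncol(x), feature_names = feature_names,
         canonicalized = !anyNA(x)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$x), " samples x ", x$n_features,
      " features (", x$task, ")\n", sep = "")
  if (x$task == "classification") {
    tab <- table(x$labels)
    cat("  classes:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  } else {
    cat("  target range: [", format(min(x$labels)), ", ",
        format(max(x$labels)), "]\n", sep = "")
  }
  nmiss <- sum(is.na(x$x))
  if (nmiss > 0) cat("  missing cells:", nmiss, "\n")
  invisible(x)
}

#' Read a delimited or ARFF dataset into a feature table
#'
#' Reads a CSV (RFC-4180, header row required) or a dense ARFF file and
#' returns a [feature_table()].  The missing-value markers `?`, the empty
#' cell and `NA` are preserved as `NA` flags; any other non-numeric feature
#' cell is a parse error naming the offending row and column.  No rows are
#' silently dropped.
#'
#' @param path path to the file.
#' @param label_column name of the label column.
#' @param format `"auto"` (by file extension), `"csv"` or `"arff"`.
#' @param task passed to [feature_table()]; `"auto"` infers from the label
#'   column type.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column,
                               format = c("auto", "csv", "arff"),
                               task = "auto") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "arff") {
    df <- foreign::read.arff(path)
  } else {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  }
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not present in ", path)
  }
  labels <- df[[label_column]]
  feats <- df[setdiff(names(df), label_column)]

  if (format == "csv") {
    # everything was read as character; coerce feature cells ourselves so a
    # bad cell is reported, not silently NA'd
    missing_markers <- c("?", "", "NA")
    for (j in seq_along(feats)) {
      col <- trimws(feats[[j]])
      is_missing <- col %in% missing_markers
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is_missing & is.na(num))
      if (length(bad) > 0) {
        stop("non-numeric value '", col[bad[1]], "' in column '",
             names(feats)[j], "', row ", bad[1])
      }
      num[is_missing] <- NA_real_
      feats[[j]] <- num
    }
    lab_trim <- trimws(labels)
    lab_num <- suppressWarnings(as.numeric(lab_trim))
    if (!anyNA(lab_num)) labels <- lab_num
  } else {
    not_num <- !vapply(feats, is.numeric, logical(1))
    if (any(not_num)) {
      stop("non-numeric ARFF feature column(s): ",
           paste(names(feats)[not_num], collapse = ", "))
    }
  }
  feature_table(as.matrix(as.data.frame(feats, check.names = FALSE)),
                labels, task = task)
}

#' Impute missing values and rescale a feature table
#'
#' Resolves every missing flag and optionally rescales each feature column,
#' leaving the labels untouched.  The operation is deterministic and
#' idempotent: applying it twice equals applying it once.
#'
#' Zero-variance columns are mapped to all-zero under both `"minmax"` and
#' `"zscore"` (guarded division) so that downstream learners never see
#' `NaN`.
#'
#' Note the wrapper scorer ([evaluate_subset()]) fits its own imputation and
#' standardization on the training folds only; global canonicalization is
#' provided for filter methods and parity experiments.
#'
#' @param table a [feature_table()].
#' @param impute `"mean"` (default), `"median"` or `"drop_row"`.
#' @param scale `"none"` (default), `"minmax"` or `"zscore"`.
#' @return A canonicalized [feature_table()] with no missing entries.
#' @export
canonicalize <- function(table,
                         impute = c("mean", "median", "drop_row"),
                         scale = c("none", "minmax", "zscore")) {
  stopifnot(inherits(table, "feature_table"))
  impute <- match.arg(impute)
  scale <- match.arg(scale)
  x <- table$x
  labels <- table$labels

  if (anyNA(x)) {
    if (impute == "drop_row") {
      keep <- !apply(x, 1L, anyNA)
      if (table$task == "classification") {
        left <- table(table$labels[keep])
        gone <- setdiff(levels(table$labels), names(left)[left > 0])
        if (length(gone) > 0) {
          stop("drop_row imputation removed every sample of class: ",
               paste(gone, collapse = ", "))
        }
      }
      if (!any(keep)) stop("drop_row imputation removed every sample")
      x <- x[keep, , drop = FALSE]
      labels <- if (is.factor(labels)) droplevels(labels[keep]) else labels[keep]
    } else {
      fun <- if (impute == "mean") mean else stats::median
      for (j in seq_len(ncol(x))) {
        miss <- is.na(x[, j])
        if (any(miss)) {
          fill <- fun(x[!miss, j])
          if (is.na(fill)) fill <- 0  # all-missing column
          x[miss, j] <- fill
        }
      }
    }
  }

  if (scale == "minmax") {
    for (j in seq_len(ncol(x))) {
      rng <- range(x[, j])
      span <- rng[2] - rng[1]
      x[, j] <- if (span > 0) (x[, j] - rng[1]) / span else rep(0, nrow(x))
    }
  } else if (scale == "zscore") {
    for (j in seq_len(ncol(x))) {
      s <- stats::sd(x[, j])
      x[, j] <- if (s > 0) (x[, j] - mean(x[, j])) / s else rep(0, nrow(x))
    }
  }

  out <- feature_table(x, labels, task = table$task,
                       feature_names = table$feature_names)
  out$canonicalized <- TRUE
  out
}

#' Write a feature table to CSV
#'
#' Writes the feature matrix plus a label column; missing entries are written
#' as `?` so that [read_feature_table()] round-trips them.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param label_column name for the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, label_column = "label") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$x, check.names = FALSE)
  df[[label_column]] <- as.character(table$labels)
  utils::write.csv(df, path, row.names = FALSE, na = "?", quote = FALSE)
  invisible(path)
}
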
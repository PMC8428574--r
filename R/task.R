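#' Create a right-censored survival task
#'
#' A survival task bundles a numeric feature matrix with a right-censored
#' survival outcome: the observed time `T_i = min(event time, censoring
#' time)` and the event indicator `delta_i` (1 = event observed, 0 =
#' right-censored).  All learners and measures in the package consume
#' this container.
#'
#' Validation is strict: dimensions must agree, times must be finite and
#' non-negative, status must be coded 0/1 (any other coding is rejected
#' rather than guessed), and missing values anywhere are an error --
#' imputation is deliberately out of scope.  Tied times are allowed and
#' preserved.
#'
#' @param X numeric matrix (or data frame coercible to one) of features,
#'   one row per subject.  Column names are kept as `feature_names`;
#'   unnamed columns are labelled `x1, x2, ...`.
#' @param time numeric vector of observed times, finite and `>= 0`.
#'   Units are arbitrary but must be consistent.
#' @param status integer/numeric vector in `{0, 1}`; 1 = event,
#'   0 = right-censored.
#' @param id character label for the task.
#'
#' @return An object of class `surv_task`: a list with elements `X`
#'   (numeric matrix), `time`, `status` (integer), `feature_names`,
#'   `n`, `p`, `censoring_type` (always `"right"` in this version; the
#'   field is reserved for future censoring types) and `id`.
#'
#' @examples
#' task <- surv_task(X = matrix(rnorm(6), ncol = 2),
#'                   time = c(1, 2, 3), status = c(1, 1, 0))
#' task_summary(task)
#' @export
surv_task <- function(X, time, status, id = "task") {
  if (is.data.frame(X)) {
    non_num <- !vapply(X, is.numeric, logical(1))
    if (any(non_num)) {
      stop("non-numeric feature column(s): ",
           paste(names(X)[non_num], collapse = ", "),
           " (categorical features must be pre-encoded)", call. = FALSE)
    }
    X <- as.matrix(X)
  }
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("'X' must be a numeric matrix or all-numeric data frame",
         call. = FALSE)
  }
  n <- nrow(X)
  if (n < 1L) stop("empty task: 'X' has zero rows", call. = FALSE)
  if (length(time) != n || length(status) != n) {
    stop(sprintf(
      "dimension mismatch: rows(X) = %d, length(time) = %d, length(status) = %d",
      n, length(time), length(status)), call. = FALSE)
  }
  time <- as.numeric(time)
  bad_t <- which(!is.finite(time) | time < 0)
  if (length(bad_t)) {
    stop("invalid 'time' (must be finite and >= 0) at row(s): ",
         paste(utils::head(bad_t, 10L), collapse = ", "), call. = FALSE)
  }
  bad_s <- which(!(status %in% c(0, 1)))
  if (length(bad_s)) {
    stop("invalid 'status' (must be 0 = censored or 1 = event) at row(s): ",
         paste(utils::head(bad_s, 10L), collapse = ", "), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)
    stop("missing/non-finite feature value at (row, col): ",
         paste(sprintf("(%d, %d)", bad[, 1L], bad[, 2L])[seq_len(min(5L, nrow(bad)))],
               collapse = ", "), call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(
    X = X,
    time = time,
    status = as.integer(status),
    feature_names = colnames(X),
    n = n,
    p = ncol(X),
    censoring_type = "right",
    id = as.character(id)[1L]
  ), class = "surv_task")
}

#' @export
print.surv_task <- function(x, ...) {
  cat(sprintf("<surv_task '%s'> n = %d, p = %d, events = %d (%.1f%% censored)\n",
              x$id, x$n, x$p, sum(x$status),
              100 * (1 - mean(x$status))))
  invisible(x)
}

#' Subset a survival task by row indices
#'
#' @param task a `surv_task`.
#' @param idx integer vector of row indices to keep.
#' @return A new `surv_task` with the selected subjects, in `idx` order.
#' @export
task_subset <- function(task, idx) {
  stopifnot(inherits(task, "surv_task"))
  surv_task(task$X[idx, , drop = FALSE], task$time[idx], task$status[idx],
            id = task$id)
}

#' Read a survival task from a CSV file
#'
#' Expects an RFC-4180 CSV with a header row.  The time and status
#' columns are named explicitly; all remaining columns are used as
#' features unless `feature_cols` narrows the selection.  Any missing or
#' non-numeric cell is an error -- no silent coercion or imputation.
#'
#' @param path path to the CSV file.
#' @param time_col,status_col names of the outcome columns.
#' @param feature_cols optional character vector of feature column
#'   names; default: every column except the outcome columns.
#' @param id task label; defaults to the file name.
#' @return A [surv_task].
#' @export
read_task_csv <- function(path, time_col = "time", status_col = "status",
                          feature_cols = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  for (col in c(time_col, status_col)) {
    if (!col %in% names(df)) {
      stop("column not found in ", path, ": '", col, "'", call. = FALSE)
    }
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(df), c(time_col, status_col))
  } else {
    missing_cols <- setdiff(feature_cols, names(df))
    if (length(missing_cols)) {
      stop("feature column(s) not found: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  feats <- df[, feature_cols, drop = FALSE]
  for (col in feature_cols) {
    v <- feats[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn))
      if (length(bad)) {
        stop(sprintf("non-numeric or missing value in column '%s' at row %d",
                     col, bad[1L]), call. = FALSE)
      }
      feats[[col]] <- vn
    }
    if (anyNA(feats[[col]])) {
      stop(sprintf("missing value in column '%s' at row %d",
                   col, which(is.na(feats[[col]]))[1L]), call. = FALSE)
    }
  }
  X <- as.matrix(feats)
  if (length(feature_cols) == 0L) {
    X <- matrix(numeric(0), nrow = nrow(df), ncol = 0L)
  }
  surv_task(X, df[[time_col]], df[[status_col]],
            id = if (is.null(id)) basename(path) else id)
}

#' Write a survival task to CSV
#'
#' Inverse of [read_task_csv()]: writes columns `time`, `status` and the
#' feature columns.  Round-tripping preserves `n`, `p`, `time`, `status`
#' and `X` up to decimal representation.
#'
#' @param task a `surv_task`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_task_csv <- function(task, path) {
  stopifnot(inherits(task, "surv_task"))
  df <- data.frame(time = task$time, status = task$status,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(task$X, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a survival task
#'
#' @param task a `surv_task`.
#' @return A list with `n`, `p`, `n_events`, `censoring_prop`
#'   (`1 - mean(status)`) and `time_range`.
#' @export
task_summary <- function(task) {
  stopifnot(inherits(task, "surv_task"))
  list(
    n = task$n,
    p = task$p,
    n_events = sum(task$status),
    censoring_prop = 1 - mean(task$status),
    time_range = range(task$time)
  )
}
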
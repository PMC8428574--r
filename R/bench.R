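# Run code under a temporary RNG state so framework-level randomness
# (fold assignment, simulation) is reproducible and never perturbs the
# caller's stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Create a k-fold cross-validation plan
#'
#' Partitions the task's subjects into `k` disjoint, exhaustive test
#' folds of near-equal size (sizes differ by at most one).  The
#' partition is a deterministic function of `seed`: repeated calls
#' reproduce it bit-exactly, and the caller's RNG state is untouched.
#' With `stratify = TRUE` the assignment is performed separately within
#' events and censored subjects, so per-fold event counts differ from
#' proportionality by at most one.
#'
#' @param task a [surv_task].
#' @param k number of folds, `2 <= k <= n`.
#' @param seed integer seed controlling the partition.
#' @param stratify stratify fold assignment by event status.
#' @return An object of class `resampling_plan` with elements `scheme`,
#'   `k`, `seed`, `stratify`, `n` and `folds` (list of `k` test-index
#'   vectors).
#' @export
make_cv <- function(task, k, seed = 1L, stratify = FALSE) {
  stopifnot(inherits(task, "surv_task"))
  n <- task$n
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  if (k > n) stop(sprintf("'k' = %d exceeds n = %d", k, n), call. = FALSE)
  assign_folds <- function(idx) {
    shuffled <- idx[sample.int(length(idx))]
    split(shuffled, rep_len(seq_len(k), length(shuffled)))
  }
  folds <- with_local_seed(seed, {
    if (stratify) {
      ev <- assign_folds(which(task$status == 1L))
      cs <- which(task$status == 0L)
      cns <- if (length(cs)) assign_folds(cs) else
        stats::setNames(rep(list(integer(0)), k), as.character(seq_len(k)))
      lapply(seq_len(k), function(f) {
        sort(c(ev[[as.character(f)]], cns[[as.character(f)]]))
      })
    } else {
      lapply(assign_folds(seq_len(n)), sort)
    }
  })
  folds <- unname(folds)
  if (any(vapply(folds, length, integer(1)) == 0L)) {
    stop("internal error: empty test fold", call. = FALSE)
  }
  structure(list(scheme = "cv", k = k, seed = as.integer(seed),
                 stratify = stratify, n = n, folds = folds),
            class = "resampling_plan")
}

#' Create a holdout plan
#'
#' A single train/test split; the test fold holds
#' `round(n * (1 - split))` subjects.
#'
#' @param task a [surv_task].
#' @param split fraction of subjects used for training, in (0, 1).
#' @param seed integer seed.
#' @return A `resampling_plan` with one fold.
#' @export
make_holdout <- function(task, split = 2 / 3, seed = 1L) {
  stopifnot(inherits(task, "surv_task"), split > 0, split < 1)
  n <- task$n
  n_test <- max(1L, n - round(n * split))
  test <- with_local_seed(seed, sort(sample.int(n, n_test)))
  structure(list(scheme = "holdout", k = 1L, seed = as.integer(seed),
                 stratify = FALSE, n = n, folds = list(test)),
            class = "resampling_plan")
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat(sprintf("<resampling_plan %s> k = %d, n = %d, seed = %d%s\n",
              x$scheme, x$k, x$n, x$seed,
              if (x$stratify) ", stratified" else ""))
  invisible(x)
}

.check_channels <- function(learner, measures) {
  for (m in measures) {
    if (!m$required_channel %in% learner$predict_types) {
      stop(sprintf(
        "learner '%s' lacks '%s' required by '%s' -- wrap it with %s",
        learner$id, m$required_channel, m$id,
        if (m$required_channel == "distr") "ppl_distrcompositor()"
        else "compose_crank()"), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Fit on the training indices, predict the test fold, score each
# measure.  G for IPCW measures is fitted on the training fold unless
# ipcw_on = "test".
.score_fold <- function(task, learner, test_idx, measures, ipcw_on) {
  train_idx <- setdiff(seq_len(task$n), test_idx)
  train <- task_subset(task, train_idx)
  test_X <- task$X[test_idx, , drop = FALSE]
  test_time <- task$time[test_idx]
  test_status <- task$status[test_idx]
  model <- learner$fit(train)
  pred <- stats::predict(model, test_X)
  if (sum(test_status) == 0L) {
    warning("test fold has zero events: scores recorded as missing",
            call. = FALSE)
    return(rep(NA_real_, length(measures)))
  }
  G <- if (identical(ipcw_on, "test")) {
    censoring_weights(test_time, test_status)
  } else {
    censoring_weights(train$time, train$status)
  }
  vapply(measures, function(m) m$fun(pred, test_time, test_status, G),
         numeric(1))
}

#' Resample a learner over a plan and score each fold
#'
#' For every fold: the learner is fitted on the training indices only,
#' predicts the held-out test fold, and each measure scores the
#' prediction.  Censoring weights for IPCW measures are estimated on
#' the training fold (no test leakage); set `ipcw_on = "test"` for
#' sensitivity analyses.  Learner/measure channel compatibility is
#' verified before any fitting.  A test fold without events is scored
#' as missing with a warning and excluded from aggregation.
#'
#' @param task a [surv_task].
#' @param learner a [lrn()] / [new_learner()] object.
#' @param plan a [make_cv()] / [make_holdout()] plan for this task.
#' @param measures a [msr()] object or list of them.
#' @param ipcw_on `"train"` (default) or `"test"`.
#' @param on_error `"stop"` (default) propagates fold failures;
#'   `"na"` records a failed fold as missing scores with the error
#'   message in the `error` column (used by [benchmark()] so one bad
#'   cell cannot abort a grid).
#' @return A data frame with columns `task`, `learner`, `fold`,
#'   `measure`, `score`, `error`.
#' @export
resample <- function(task, learner, plan, measures, ipcw_on = "train",
                     on_error = c("stop", "na")) {
  stopifnot(inherits(task, "surv_task"), inherits(learner, "surv_learner"),
            inherits(plan, "resampling_plan"))
  on_error <- match.arg(on_error)
  if (inherits(measures, "surv_measure")) measures <- list(measures)
  stopifnot(all(vapply(measures, inherits, logical(1), "surv_measure")))
  if (plan$n != task$n) {
    stop("plan was built for a task of different size", call. = FALSE)
  }
  .check_channels(learner, measures)
  rows <- lapply(seq_along(plan$folds), function(f) {
    err <- NA_character_
    scores <- if (on_error == "na") {
      tryCatch(
        .score_fold(task, learner, plan$folds[[f]], measures, ipcw_on),
        error = function(e) {
          err <<- conditionMessage(e)
          rep(NA_real_, length(measures))
        })
    } else {
      .score_fold(task, learner, plan$folds[[f]], measures, ipcw_on)
    }
    data.frame(task = task$id, learner = learner$id, fold = f,
               measure = vapply(measures, `[[`, character(1), "id"),
               score = scores, error = err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-fold scores
#'
#' Macro-average: the aggregate is the arithmetic mean of the fold
#' scores (missing folds excluded), with its standard deviation.
#'
#' @param scores a data frame from [resample()] or
#'   `benchmark()$scores`.
#' @return A data frame with one row per (task, learner, measure):
#'   `mean_score`, `sd_score`, `n_folds` (non-missing folds).
#' @export
aggregate_scores <- function(scores) {
  key <- interaction(scores$task, scores$learner, scores$measure,
                     drop = TRUE)
  parts <- split(scores, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    ok <- !is.na(d$score)
    data.frame(task = d$task[1L], learner = d$learner[1L],
               measure = d$measure[1L],
               mean_score = mean(d$score[ok]),
               sd_score = stats::sd(d$score[ok]),
               n_folds = sum(ok), stringsAsFactors = FALSE)
    }))
  out <- out[order(out$task, out$learner, out$measure), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benchmark learners across tasks under a shared resampling scheme
#'
#' Runs the full factorial grid tasks x learners under `k`-fold
#' cross-validation.  Within a task all learners see *identical* fold
#' indices (paired comparison).  A learner failing on a fold is
#' recorded as a failed cell (score `NA`, message kept in the `error`
#' column) without aborting the rest of the grid.
#'
#' @param tasks a [surv_task] or list of them.
#' @param learners a learner or list of learners.
#' @param measures a measure or list of measures.
#' @param k folds for cross-validation.
#' @param seed integer seed shared by every task's fold assignment.
#' @param stratify stratify folds by event status.
#' @param ipcw_on `"train"` (default) or `"test"`.
#' @return An object of class `benchmark_result`: list with `scores`
#'   (per-fold rows, sorted by task/learner/measure) and `aggregates`
#'   (from [aggregate_scores()]).
#' @export
benchmark <- function(tasks, learners, measures, k = 3L, seed = 1L,
                      stratify = FALSE, ipcw_on = "train") {
  if (inherits(tasks, "surv_task")) tasks <- list(tasks)
  if (inherits(learners, "surv_learner")) learners <- list(learners)
  if (inherits(measures, "surv_measure")) measures <- list(measures)
  stopifnot(length(tasks) >= 1L, length(learners) >= 1L,
            length(measures) >= 1L)
  all_rows <- list()
  for (task in tasks) {
    plan <- make_cv(task, k = k, seed = seed, stratify = stratify)
    for (learner in learners) {
      rows <- tryCatch(
        resample(task, learner, plan, measures, ipcw_on = ipcw_on,
                 on_error = "na"),
        error = function(e) {
          data.frame(task = task$id, learner = learner$id,
                     fold = rep(seq_len(plan$k),
                                each = length(measures)),
                     measure = rep(vapply(measures, `[[`, character(1),
                                          "id"), plan$k),
                     score = NA_real_,
                     error = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
      all_rows[[length(all_rows) + 1L]] <- rows
    }
  }
  scores <- do.call(rbind, all_rows)
  scores <- scores[order(scores$task, scores$learner, scores$fold,
                         scores$measure), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores, aggregates = aggregate_scores(scores)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$aggregates)
  invisible(x)
}
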
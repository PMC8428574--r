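# Shared risk-set table: unique event times t_j with event counts d_j
# and at-risk counts n_j = #{i : T_i >= t_j}.
event_table <- function(time, status) {
  et <- sort(unique(time[status == 1L]))
  if (!length(et)) {
    return(list(times = numeric(0), d = integer(0), n_risk = integer(0)))
  }
  d <- tabulate(match(time[status == 1L], et), nbins = length(et))
  # n_risk = n - #{T_i < t_j}, via exact comparisons on the sorted times
  n_risk <- length(time) - findInterval(et, sort(time), left.open = TRUE)
  list(times = et, d = d, n_risk = n_risk)
}

#' Fit the Kaplan-Meier product-limit estimator
#'
#' Estimates the marginal survival function
#' `S(t) = prod_{t_j <= t} (1 - d_j / n_j)` over the unique event times
#' `t_j` of the training data, with `d_j` events at `t_j` and `n_j`
#' subjects still at risk (`T_i >= t_j`).  Ties are preserved, not
#' jittered.  With zero events the estimator is the constant curve
#' `S == 1` (a warning is raised, not an error).
#'
#' Prediction replicates the single fitted curve for every test subject
#' (`distr` channel) and sets `crank = -RMST` of the curve, identical
#' across subjects: the marginal estimator carries no discrimination.
#'
#' @param task a [surv_task].
#' @return An object of class `km_model` with elements `grid` (event
#'   times), `surv` (survival probabilities) and `predict_types`.
#' @examples
#' task <- surv_task(matrix(0, 3, 1), time = c(1, 2, 3),
#'                   status = c(1, 1, 0))
#' fit_kaplan_meier(task)$surv   # 2/3, 1/3, 1/3
#' @export
fit_kaplan_meier <- function(task) {
  stopifnot(inherits(task, "surv_task"))
  et <- event_table(task$time, task$status)
  if (!length(et$times)) {
    warning("no events in training data: Kaplan-Meier curve is S == 1",
            call. = FALSE)
    grid <- sort(unique(task$time))
    surv <- rep(1, length(grid))
  } else {
    grid <- et$times
    surv <- cumprod(1 - et$d / et$n_risk)
  }
  structure(list(grid = grid, surv = surv, id = "surv.kaplan",
                 predict_types = c("crank", "distr")),
            class = c("km_model", "survkit_model"))
}

#' Fit the Nelson-Aalen cumulative-hazard estimator
#'
#' Estimates `H(t) = sum_{t_j <= t} d_j / n_j` on the unique event
#' times of the training data and reports survival through
#' `S(t) = exp(-H(t))`.  `exp(-H)` dominates the Kaplan-Meier curve
#' pointwise on any dataset (since `exp(-x) >= 1 - x`).  Prediction is
#' as for [fit_kaplan_meier()].
#'
#' @param task a [surv_task].
#' @return An object of class `na_model` with `grid`, `cumhaz`, `surv`.
#' @export
fit_nelson_aalen <- function(task) {
  stopifnot(inherits(task, "surv_task"))
  et <- event_table(task$time, task$status)
  if (!length(et$times)) {
    warning("no events in training data: Nelson-Aalen H == 0", call. = FALSE)
    grid <- sort(unique(task$time))
    cumhaz <- rep(0, length(grid))
  } else {
    grid <- et$times
    cumhaz <- cumsum(et$d / et$n_risk)
  }
  structure(list(grid = grid, cumhaz = cumhaz, surv = exp(-cumhaz),
                 id = "surv.nelson",
                 predict_types = c("crank", "distr")),
            class = c("na_model", "survkit_model"))
}

# Replicate a single marginal curve for each test subject.
.predict_marginal <- function(grid, surv, n, id) {
  S <- matrix(rep(surv, each = n), nrow = n)
  distr <- surv_distribution(grid, S)
  surv_prediction(crank = rep(-dist_mean(distr)[1L], n), distr = distr,
                  learner_id = id)
}

#' @export
predict.km_model <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata)) nrow(newdata) else as.integer(newdata)
  .predict_marginal(object$grid, object$surv, n, object$id)
}

#' @export
predict.na_model <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata)) nrow(newdata) else as.integer(newdata)
  .predict_marginal(object$grid, object$surv, n, object$id)
}

#' @export
print.survkit_model <- function(x, ...) {
  cat(sprintf("<%s> ('%s')\n", class(x)[1L], x$id))
  invisible(x)
}
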
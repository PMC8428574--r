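#' Kaplan-Meier censoring weights for IPCW measures
#'
#' Fits the product-limit estimator to the *censoring* distribution by
#' flipping the event indicator ("event" = censored), yielding
#' `G(t) = P(C > t)`.  All inverse-probability-of-censoring-weighted
#' (IPCW) measures draw their weights from this object.  Event-time
#' weights use the left limit `G(t-)`, the standard convention;
#' denominators are clamped below at `floor` to bound the weights, and
#' the number of floored terms is reported via `message()` when any
#' occur.
#'
#' @param time,status training times and event indicators (1 = event,
#'   0 = censored).  Typically the *training* fold, so evaluation never
#'   peeks at test outcomes.
#' @param floor minimum weight denominator (default `1e-3`).
#' @return An object of class `censoring_weights` with `grid`
#'   (censoring times), `G` (survival probabilities) and `floor`.
#' @export
censoring_weights <- function(time, status, floor = 1e-3) {
  stopifnot(length(time) == length(status), floor > 0)
  ct <- sort(unique(time[status == 0L]))
  if (!length(ct)) {
    G <- numeric(0)
  } else {
    d <- tabulate(match(time[status == 0L], ct), nbins = length(ct))
    n_risk <- length(time) - findInterval(ct, sort(time), left.open = TRUE)
    G <- cumprod(1 - d / n_risk)
  }
  structure(list(grid = ct, G = G, floor = floor),
            class = "censoring_weights")
}

#' Evaluate the censoring survival function
#'
#' @param cw a [censoring_weights] object.
#' @param times evaluation times.
#' @param left_limit evaluate `G(t-)` (value just before `t`) instead of
#'   the right-continuous `G(t)`.
#' @param clamp clamp below at `cw$floor` (with a message counting
#'   floored values).
#' @return Numeric vector of probabilities.
#' @export
eval_G <- function(cw, times, left_limit = FALSE, clamp = TRUE) {
  stopifnot(inherits(cw, "censoring_weights"))
  if (!length(cw$grid)) {
    out <- rep(1, length(times))
  } else {
    k <- findInterval(times, cw$grid, left.open = left_limit)
    out <- ifelse(k == 0L, 1, cw$G[pmax(k, 1L)])
  }
  if (clamp) {
    n_floored <- sum(out < cw$floor)
    if (n_floored > 0L) {
      message(sprintf("censoring weights: %d denominator(s) floored at %g",
                      n_floored, cw$floor))
    }
    out <- pmax(out, cw$floor)
  }
  out
}

# Common IPCW scoring-rule skeleton over an evaluation grid:
#   score(t) = (1/n) sum_i [ dead_loss(S_i(t)) * 1(T_i <= t, d_i = 1) / G(T_i-)
#                          + alive_loss(S_i(t)) * 1(T_i > t)        / G(t) ]
# Censored subjects with T_i <= t contribute zero.  The integrated
# variant is the trapezoid average over the grid, normalized by its
# range; a single evaluation time returns that time's score.
.ipcw_score <- function(distr, time, status, G, eval_times, integrated,
                        dead_loss, alive_loss) {
  stopifnot(inherits(distr, "surv_distribution"),
            inherits(G, "censoring_weights"))
  n <- nrow(distr$S)
  if (length(time) != n || length(status) != n) {
    stop("time/status length must match the number of predicted curves",
         call. = FALSE)
  }
  if (is.null(eval_times)) eval_times <- sort(unique(time[status == 1L]))
  eval_times <- sort(unique(as.numeric(eval_times)))
  if (!length(eval_times)) {
    stop("empty evaluation grid (no event times supplied or observed)",
         call. = FALSE)
  }
  St <- eval_survival(distr, eval_times)           # n x m
  w_dead <- 1 / eval_G(G, time, left_limit = TRUE) # per subject
  w_alive <- 1 / eval_G(G, eval_times)             # per eval time
  m <- length(eval_times)
  dead <- (matrix(time, n, m) <= matrix(eval_times, n, m, byrow = TRUE)) &
    (status == 1L)
  alive <- matrix(time, n, m) > matrix(eval_times, n, m, byrow = TRUE)
  contrib <- dead_loss(St) * dead * w_dead +
    alive_loss(St) * alive * matrix(w_alive, n, m, byrow = TRUE)
  score_t <- colMeans(contrib)
  if (!integrated) return(stats::setNames(score_t, eval_times))
  if (m == 1L) return(unname(score_t))
  dt <- diff(eval_times)
  sum((score_t[-1L] + score_t[-m]) / 2 * dt) / (eval_times[m] - eval_times[1L])
}

#' Integrated Graf (Brier) score
#'
#' The IPCW squared-error scoring rule for survival-distribution
#' predictions: at each evaluation time `t`, subjects with an observed
#' event by `t` contribute `S_i(t)^2 / G(T_i-)`, subjects still at risk
#' contribute `(1 - S_i(t))^2 / G(t)`, and censored-by-`t` subjects
#' contribute zero.  `integrated = TRUE` (default) averages over the
#' evaluation grid by the trapezoid rule normalized to the grid range.
#' Lower is better; 0 is a sharp, correct prediction.
#'
#' @param distr a [surv_distribution] of per-subject predicted curves.
#' @param time,status observed test outcomes.
#' @param G a [censoring_weights] object (fit it on the training data).
#' @param eval_times evaluation grid; default = unique test event times.
#' @param integrated return the integrated score (scalar) or the
#'   per-time curve (named vector).
#' @return Scalar score (or per-time vector when `integrated = FALSE`).
#' @export
graf_score <- function(distr, time, status, G, eval_times = NULL,
                       integrated = TRUE) {
  .ipcw_score(distr, time, status, G, eval_times, integrated,
              dead_loss = function(S) S^2,
              alive_loss = function(S) (1 - S)^2)
}

#' Integrated survival log-loss
#'
#' Same IPCW skeleton as [graf_score()] with the squared error replaced
#' by the log loss: `-log(1 - S_i(t))` for subjects with an observed
#' event by `t`, `-log S_i(t)` for subjects at risk past `t`, both
#' clamped by `eps = 1e-15`.  The non-integrated log-loss at a single
#' time is obtained with `eval_times = t0, integrated = FALSE`.
#'
#' @inheritParams graf_score
#' @return Scalar score `>= 0` (or per-time vector).
#' @export
integrated_logloss <- function(distr, time, status, G, eval_times = NULL,
                               integrated = TRUE) {
  .ipcw_score(distr, time, status, G, eval_times, integrated,
              dead_loss = function(S) -log(pmax(1 - S, .surv_eps)),
              alive_loss = function(S) -log(pmax(S, .surv_eps)))
}

#' Integrated Schmid (absolute) score
#'
#' The IPCW absolute-error scoring rule: `S_i(t)` for subjects dead by
#' `t`, `1 - S_i(t)` for subjects at risk, weighted and integrated as
#' in [graf_score()].
#'
#' @inheritParams graf_score
#' @return Scalar score in `[0, 1]` (or per-time vector).
#' @export
schmid_score <- function(distr, time, status, G, eval_times = NULL,
                         integrated = TRUE) {
  .ipcw_score(distr, time, status, G, eval_times, integrated,
              dead_loss = function(S) S,
              alive_loss = function(S) 1 - S)
}

#' Harrell's concordance index
#'
#' The proportion of comparable pairs ranked concordantly by `crank`.
#' A pair `(i, j)` is comparable iff `T_i < T_j` and subject `i` is
#' uncensored; it is concordant iff `crank_i > crank_j` (higher crank =
#' higher risk); crank ties count 0.5.
#'
#' @param crank risk ranking, higher = higher risk.
#' @param time,status observed outcomes.
#' @return Scalar in `[0, 1]`; 0.5 is uninformative.
#' @export
harrell_c <- function(crank, time, status) {
  n <- length(time)
  stopifnot(length(crank) == n, length(status) == n)
  comp <- outer(time, time, "<") & (status == 1L)       # [i, j]
  conc <- outer(crank, crank, ">")
  ties <- outer(crank, crank, "==")
  n_comp <- sum(comp)
  if (n_comp == 0L) {
    stop("no comparable pairs (all subjects censored or tied)",
         call. = FALSE)
  }
  (sum(conc & comp) + 0.5 * sum(ties & comp)) / n_comp
}

#' Uno's IPCW concordance index
#'
#' Harrell-style concordance with each comparable pair `(i, j)` (where
#' `i` is the earlier, uncensored member with `T_i < tau`) weighted by
#' `1 / G(T_i-)^2`, removing the censoring-distribution dependence of
#' the plain concordance index.  With no censoring (`G == 1`) it equals
#' [harrell_c()] exactly.
#'
#' @inheritParams harrell_c
#' @param G a [censoring_weights] object.
#' @param tau truncation time; pairs with `T_i >= tau` are excluded.
#'   Default: the maximum observed event time.
#' @return Scalar in `[0, 1]`.
#' @export
uno_c <- function(crank, time, status, G, tau = NULL) {
  n <- length(time)
  stopifnot(length(crank) == n, length(status) == n,
            inherits(G, "censoring_weights"))
  if (is.null(tau)) {
    if (!any(status == 1L)) stop("no events: tau undefined", call. = FALSE)
    tau <- max(time[status == 1L])
  }
  w <- 1 / eval_G(G, time, left_limit = TRUE)^2
  comp <- outer(time, time, "<") & (status == 1L) & (time < tau)
  if (!any(comp)) stop("no comparable pairs", call. = FALSE)
  conc <- outer(crank, crank, ">")
  ties <- outer(crank, crank, "==")
  wmat <- matrix(w, n, n)
  denom <- sum(wmat * comp)
  if (denom <= 0) stop("zero total IPCW weight", call. = FALSE)
  sum(wmat * comp * (conc + 0.5 * ties)) / denom
}

#' Uno's IPCW cumulative/dynamic time-dependent AUC
#'
#' At horizon `t`, cases are subjects with an observed event by `t`
#' (`T_i <= t`, uncensored), weighted by `1 / G(T_i-)`; controls are
#' subjects still at risk (`T_j > t`).  The AUC is the weighted
#' proportion of case/control pairs ranked correctly by the marker,
#' ties counting 0.5.
#'
#' @param marker risk marker (typically `crank`), higher = higher risk.
#' @param time,status observed outcomes.
#' @param G a [censoring_weights] object.
#' @param t evaluation horizon.
#' @return Scalar in `[0, 1]`.
#' @export
uno_auc <- function(marker, time, status, G, t) {
  n <- length(time)
  stopifnot(length(marker) == n, length(status) == n, length(t) == 1L)
  cases <- which(time <= t & status == 1L)
  controls <- which(time > t)
  if (!length(cases)) stop("no cases (events by t) at t = ", t, call. = FALSE)
  if (!length(controls)) stop("no controls (at risk past t) at t = ", t,
                              call. = FALSE)
  w <- 1 / eval_G(G, time[cases], left_limit = TRUE)
  mi <- marker[cases]
  mj <- marker[controls]
  conc <- outer(mi, mj, ">") + 0.5 * outer(mi, mj, "==")
  sum(w * rowSums(conc)) / (sum(w) * length(controls))
}

#' Van Houwelingen's calibration slope
#'
#' Refits a single-covariate Cox model on validation data with the
#' predicted linear predictor as the only covariate and returns its
#' coefficient.  A perfectly calibrated model has slope 1; slopes below
#' 1 indicate overfitting (effects too large), above 1 underfitting.
#'
#' @param lp predicted linear predictors on the validation subjects
#'   (must be non-constant).
#' @param time,status validation outcomes (at least one event).
#' @return The Cox slope coefficient (scalar).
#' @export
houwelingen_beta <- function(lp, time, status) {
  if (stats::sd(lp) == 0) {
    stop("constant lp: calibration slope undefined", call. = FALSE)
  }
  task <- surv_task(matrix(lp, ncol = 1L,
                           dimnames = list(NULL, "lp")),
                    time, status, id = "calibration")
  unname(fit_coxph(task)$beta)
}

#' Kaplan-Meier calibration discrepancy
#'
#' Numeric counterpart of the visual check that compares the average
#' predicted survival curve with the Kaplan-Meier estimate of the test
#' data: returns `max_t | mean_i S_i(t) - KM(t) |` over the KM grid.
#' The full curve pair is attached as attributes `"times"`,
#' `"mean_curve"` and `"km_curve"` for plotting.
#'
#' @param distr predicted [surv_distribution] for the test subjects.
#' @param time,status test outcomes.
#' @return Scalar discrepancy `>= 0` with curve attributes.
#' @export
km_calibration <- function(distr, time, status) {
  stopifnot(inherits(distr, "surv_distribution"))
  et <- event_table(time, status)
  if (!length(et$times)) {
    grid <- sort(unique(time))
    km <- rep(1, length(grid))
  } else {
    grid <- et$times
    km <- cumprod(1 - et$d / et$n_risk)
  }
  mean_curve <- colMeans(eval_survival(distr, grid))
  out <- max(abs(mean_curve - km))
  attr(out, "times") <- grid
  attr(out, "mean_curve") <- mean_curve
  attr(out, "km_curve") <- km
  out
}
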
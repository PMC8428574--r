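# Beta-independent pieces of the Breslow partial likelihood: unique
# event times t_j, event counts d_j, within-tie covariate sums s_j, and
# the risk-set cutoffs in descending-time order.
cox_precompute <- function(Xc, time, status) {
  n <- nrow(Xc)
  ord <- order(time, decreasing = TRUE)
  et <- sort(unique(time[status == 1L]))
  ev <- which(status == 1L)
  grp <- match(time[ev], et)
  d <- tabulate(grp, nbins = length(et))
  sx <- rowsum(Xc[ev, , drop = FALSE], grp)      # J x p tie sums
  # position of the last at-risk subject (T_i >= t_j) in descending order
  pos <- n - findInterval(et, sort(time), left.open = TRUE)
  list(Xs = Xc[ord, , drop = FALSE], et = et, d = d, sx = sx, pos = pos,
       pairs = which(upper.tri(diag(ncol(Xc)), diag = TRUE),
                     arr.ind = TRUE))
}

# Breslow partial log-likelihood, score and information at beta, via
# cumulative sums over descending time order.  Returns the risk-set
# sums S0_j needed by the Breslow baseline as a by-product.
cox_pl_parts <- function(pre, beta) {
  Xs <- pre$Xs
  p <- ncol(Xs)
  r <- exp(as.vector(Xs %*% beta))
  cum0 <- cumsum(r)
  cum1 <- apply(Xs * r, 2L, cumsum)
  if (p == 1L) cum1 <- matrix(cum1, ncol = 1L)
  s0 <- cum0[pre$pos]
  s1 <- cum1[pre$pos, , drop = FALSE]
  xbar <- s1 / s0
  loglik <- sum(pre$sx %*% beta) - sum(pre$d * log(s0))
  grad <- colSums(pre$sx) - colSums(pre$d * xbar)
  info <- matrix(0, p, p)
  for (q in seq_len(nrow(pre$pairs))) {
    a <- pre$pairs[q, 1L]
    b <- pre$pairs[q, 2L]
    s2ab <- cumsum(Xs[, a] * Xs[, b] * r)[pre$pos]
    val <- sum(pre$d * (s2ab / s0 - xbar[, a] * xbar[, b]))
    info[a, b] <- val
    info[b, a] <- val
  }
  list(loglik = loglik, grad = grad, info = info,
       event_times = pre$et, S0 = s0)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Breslow-tie partial likelihood by Newton-Raphson with
#' step-halving, starting from `beta = 0` on internally centered
#' features.  Convergence is declared when the maximum absolute score
#' component falls below `tol`.  A coefficient path escaping
#' `|beta_j| * sd(x_j) > diverge_bound` -- a hazard ratio beyond
#' `exp(diverge_bound)` per covariate standard deviation, unreachable
#' for any realistic effect -- signals monotone-likelihood divergence
#' (infinite MLE, e.g. a covariate that perfectly separates early from
#' late deaths) and raises an error naming the offending covariate;
#' the bound is on the standardized scale so detection does not depend
#' on covariate units.  The baseline
#' cumulative hazard is the Breslow estimator
#' `H_0(t) = sum_{t_j <= t} d_j / sum_{i in R(t_j)} exp(x_i' beta)`
#' on the grid of unique training event times.
#'
#' Prediction channels: `lp_i = (x_i - train_mean)' beta` (centered
#' scale), `crank = lp` (higher lp = higher hazard = higher risk), and
#' `distr` through `S_i(t) = exp(-H_0(t))^{exp(lp_i)}`.
#'
#' @param task a [surv_task] with `n >= 2`, at least one event, and no
#'   constant feature column.
#' @param tol convergence tolerance on the max absolute gradient.
#' @param max_iter Newton iteration cap.
#' @param diverge_bound standardized coefficient magnitude
#'   (`|beta_j| * sd(x_j)`) treated as divergence.
#' @return An object of class `cox_model`: `beta`, `train_mean`,
#'   `baseline_times`, `baseline_cumhazard`, `loglik`, `convergence`
#'   (iterations, final gradient norm).
#' @examples
#' task <- surv_task(matrix(c(1, 1, 0, 0), ncol = 1),
#'                   time = 1:4, status = rep(1L, 4))
#' fit_coxph(task)$beta
#' @export
fit_coxph <- function(task, tol = 1e-9, max_iter = 100L,
                      diverge_bound = 10) {
  stopifnot(inherits(task, "surv_task"))
  if (task$n < 2L) stop("Cox model needs n >= 2", call. = FALSE)
  if (sum(task$status) < 1L) {
    stop("Cox model needs at least one event", call. = FALSE)
  }
  if (task$p < 1L) stop("Cox model needs at least one feature", call. = FALSE)
  train_mean <- colMeans(task$X)
  Xc <- sweep(task$X, 2L, train_mean)
  const <- which(apply(Xc, 2L, function(v) all(abs(v) < 1e-12)))
  if (length(const)) {
    stop("constant covariate(s) give a singular information matrix: ",
         paste(task$feature_names[const], collapse = ", "), call. = FALSE)
  }

  p <- ncol(Xc)
  sdx <- apply(Xc, 2L, stats::sd)
  pre <- cox_precompute(Xc, task$time, task$status)
  beta <- numeric(p)
  parts <- cox_pl_parts(pre, beta)
  iter <- 0L
  repeat {
    if (max(abs(parts$grad)) <= tol || iter >= max_iter) break
    iter <- iter + 1L
    step <- tryCatch(solve(parts$info, parts$grad), error = function(e) {
      stop("singular information matrix in Newton-Raphson step",
           call. = FALSE)
    })
    # step-halving: insist on a (weak) increase of the partial likelihood
    halve <- 0L
    repeat {
      cand <- beta + step
      cand_parts <- cox_pl_parts(pre, cand)
      if (cand_parts$loglik >= parts$loglik - 1e-12) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 30L) {
        stop(sprintf(
          "Cox fit failed to increase the partial likelihood (|grad| = %.3g)",
          max(abs(parts$grad))), call. = FALSE)
      }
    }
    beta <- cand
    parts <- cand_parts
    std_beta <- abs(beta) * sdx
    if (any(std_beta > diverge_bound)) {
      worst <- which.max(std_beta)
      stop(sprintf(
        "monotone-likelihood divergence: standardized |coefficient| of '%s' exceeds %g",
        task$feature_names[worst], diverge_bound), call. = FALSE)
    }
  }
  if (max(abs(parts$grad)) > tol) {
    stop(sprintf(
      "Cox fit did not converge in %d iterations (|grad| = %.3g)",
      max_iter, max(abs(parts$grad))), call. = FALSE)
  }

  et <- parts$event_times
  H0 <- cumsum(pre$d / parts$S0)

  structure(list(
    beta = stats::setNames(beta, task$feature_names),
    train_mean = train_mean,
    baseline_times = et,
    baseline_cumhazard = H0,
    loglik = parts$loglik,
    convergence = list(iterations = iter,
                       grad_norm = max(abs(parts$grad))),
    id = "surv.coxph",
    predict_types = c("lp", "crank", "distr")
  ), class = c("cox_model", "survkit_model"))
}

#' @export
predict.cox_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  Xc <- sweep(newdata, 2L, object$train_mean)
  lp <- as.vector(Xc %*% object$beta)
  S0 <- exp(-object$baseline_cumhazard)
  S <- outer(exp(lp), object$baseline_cumhazard,
             function(r, h) exp(-h * r))
  surv_prediction(crank = lp, lp = lp,
                  distr = surv_distribution(object$baseline_times, S),
                  learner_id = object$id)
}
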
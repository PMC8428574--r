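#' Discrete-time survival distribution objects
#'
#' The `distr` prediction type: per-subject survival curves represented
#' as right-continuous step functions on a shared, strictly increasing
#' time grid.  Row `i` of `S` gives `S_i(t_k)` at grid point `t_k`.
#'
#' Evaluation convention (shared by every consumer in the package):
#' `S_i(t) = 1` for `t < t_1`; `S_i(t) = S[i, k]` for
#' `t in [t_k, t_{k+1})`; `S_i(t) = S[i, m]` for `t >= t_m`.
#' No interpolation between grid points is performed -- the curve is the
#' step function, matching product-limit estimators.
#'
#' @param grid strictly increasing numeric vector of time points,
#'   all `>= 0`.
#' @param S numeric matrix, `n` subjects by `length(grid)` columns, with
#'   entries in `[0, 1]`, non-increasing along each row.  A vector is
#'   taken as a single row.
#' @return An object of class `surv_distribution`.
#' @examples
#' d <- surv_distribution(c(1, 2, 3), c(0.9, 0.5, 0.1))
#' eval_survival(d, c(0.5, 2.7, 10))   # 1.0, 0.5, 0.1
#' dist_mean(d)                        # 2.4
#' @export
surv_distribution <- function(grid, S) {
  grid <- as.numeric(grid)
  if (length(grid) < 1L) stop("'grid' must be non-empty", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < 0)) {
    stop("'grid' must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("'grid' must be strictly increasing", call. = FALSE)
  }
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
  if (ncol(S) != length(grid)) {
    stop(sprintf("ncol(S) = %d does not match length(grid) = %d",
                 ncol(S), length(grid)), call. = FALSE)
  }
  if (anyNA(S) || any(S < -1e-12) || any(S > 1 + 1e-12)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  S <- pmin(pmax(S, 0), 1)
  if (ncol(S) > 1L) {
    dS <- S[, -1L, drop = FALSE] - S[, -ncol(S), drop = FALSE]
    if (any(dS > 1e-10)) {
      stop("survival curves must be non-increasing along each row",
           call. = FALSE)
    }
    # forgive tiny positive drifts from floating arithmetic
    if (any(dS > 0)) {
      for (k in 2:ncol(S)) S[, k] <- pmin(S[, k], S[, k - 1L])
    }
  }
  structure(list(grid = grid, S = unname(S)), class = "surv_distribution")
}

#' @export
print.surv_distribution <- function(x, ...) {
  cat(sprintf("<surv_distribution> %d subject(s) on %d grid points [%g, %g]\n",
              nrow(x$S), length(x$grid), x$grid[1L],
              x$grid[length(x$grid)]))
  invisible(x)
}

#' Number of subjects in a distribution
#' @param dist a `surv_distribution`.
#' @return Integer row count.
#' @export
dist_n <- function(dist) nrow(dist$S)

.check_eval_times <- function(times) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("evaluation times must be finite and >= 0", call. = FALSE)
  }
  times
}

#' Evaluate survival curves at arbitrary times
#'
#' @param dist a [surv_distribution].
#' @param times numeric vector of evaluation times, finite and `>= 0`.
#' @return An `n x length(times)` matrix of survival probabilities under
#'   the step-function convention.
#' @export
eval_survival <- function(dist, times) {
  stopifnot(inherits(dist, "surv_distribution"))
  times <- .check_eval_times(times)
  # findInterval: k such that grid[k] <= t < grid[k+1]; 0 below grid
  k <- findInterval(times, dist$grid)
  out <- matrix(1, nrow = nrow(dist$S), ncol = length(times))
  pos <- which(k > 0L)
  if (length(pos)) out[, pos] <- dist$S[, k[pos], drop = FALSE]
  out
}

#' Evaluate cumulative distribution functions
#'
#' `F(t) = 1 - S(t)` pointwise.
#' @inheritParams eval_survival
#' @return Matrix of event probabilities by time `t`.
#' @export
eval_cdf <- function(dist, times) 1 - eval_survival(dist, times)

#' Evaluate cumulative hazard functions
#'
#' `H(t) = -log(max(S(t), eps))` with the package-wide clamp
#' `eps = 1e-15`, so `H` is finite even where the curve reaches zero.
#' @inheritParams eval_survival
#' @return Matrix of cumulative hazards.
#' @export
eval_cumhazard <- function(dist, times) {
  -log(pmax(eval_survival(dist, times), .surv_eps))
}

#' Restricted mean survival time of each curve
#'
#' Integrates the step function over `[0, t_m]`:
#' `mean_i = t_1 + sum_{k=2..m} (t_k - t_{k-1}) * S[i, k-1]`,
#' i.e. the restricted mean survival time (RMST) on the grid's span.
#' When `S(t_m) > 0` the unrestricted mean is not identified from the
#' curve; the value saturates at the grid end rather than extrapolating.
#'
#' @param dist a [surv_distribution].
#' @return Numeric vector, one RMST per subject.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "surv_distribution"))
  g <- dist$grid
  m <- length(g)
  if (m == 1L) return(rep(g[1L], nrow(dist$S)))
  widths <- diff(g)
  g[1L] + as.vector(dist$S[, -m, drop = FALSE] %*% widths)
}

#' Median survival time of each curve
#'
#' The smallest grid time `t_k` with `S[i, k] <= 0.5`; if the curve
#' never crosses 0.5 on the grid the value saturates at `t_m`.
#'
#' @param dist a [surv_distribution].
#' @return Numeric vector of median times.
#' @export
dist_median <- function(dist) {
  stopifnot(inherits(dist, "surv_distribution"))
  g <- dist$grid
  m <- length(g)
  apply(dist$S, 1L, function(s) {
    k <- which(s <= 0.5)
    if (length(k)) g[k[1L]] else g[m]
  })
}

#' Write a survival distribution to CSV
#'
#' First column is the grid, then one column per subject
#' (`S1, S2, ...`).
#' @param dist a [surv_distribution].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "surv_distribution"))
  df <- data.frame(time = dist$grid, t(dist$S))
  names(df) <- c("time", paste0("S", seq_len(nrow(dist$S))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival distribution written by [write_distribution_csv()]
#' @param path CSV path.
#' @return A [surv_distribution].
#' @export
read_distribution_csv <- function(path) {
  df <- utils::read.csv(path)
  surv_distribution(df$time, t(as.matrix(df[, -1L, drop = FALSE])))
}
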
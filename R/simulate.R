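#' Specify a synthetic right-censored survival-data generator
#'
#' Configures the generative model used by [simulate_surv()]:
#' covariates are i.i.d. standard normal, effects are linear
#' (`eta_i = x_i' beta`), and event times follow either a
#' proportional-hazards or an accelerated-failure-time mechanism over
#' an exponential or Weibull baseline:
#'
#' * `model = "ph"`, exponential baseline (rate `lambda`):
#'   `T* = -log(U) / (lambda * exp(eta))`.
#' * `model = "ph"`, Weibull baseline (shape `gamma_w`, scale `s`):
#'   `T* = (-log(U) / (lambda_w * exp(eta)))^(1/gamma_w)` with
#'   `lambda_w = s^(-gamma_w)`.
#' * `model = "aft"`: `log T* = log(s) + eta + (1/gamma_w) * W`, `W`
#'   standard Gumbel-minimum (an exponential baseline is the
#'   `gamma_w = 1`, `s = 1/lambda` special case).
#'
#' Censoring is independent: exponential with rate `censor_rate`,
#' administrative at `admin_time`, or absent.  Alternatively set
#' `target_censor_prop` and run [calibrate_censoring()] to solve for
#' the exponential censoring rate achieving that marginal censoring
#' proportion.
#'
#' @param n number of subjects.
#' @param beta numeric effect vector; its length sets the number of
#'   covariates `p` (may be length 0 for a null model with `p = 1`
#'   noise covariate -- pass `beta = 0` explicitly for that).
#' @param model `"ph"` or `"aft"`.
#' @param baseline `"exponential"` or `"weibull"`.
#' @param rate exponential baseline rate `lambda > 0`.
#' @param shape,scale Weibull baseline shape `gamma_w > 0` and scale
#'   `s > 0`.
#' @param censoring `"none"`, `"exponential"` or `"admin"`.
#' @param censor_rate exponential censoring rate (required when
#'   `censoring = "exponential"` unless calibrated).
#' @param admin_time administrative censoring time (for
#'   `censoring = "admin"`).
#' @param target_censor_prop optional target censoring proportion in
#'   (0, 1), resolved by [calibrate_censoring()].
#' @param seed integer seed; identical configs give bit-identical data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n, beta = 0, model = c("ph", "aft"),
                       baseline = c("exponential", "weibull"),
                       rate = 1, shape = 1.5, scale = 1,
                       censoring = c("none", "exponential", "admin"),
                       censor_rate = NULL, admin_time = NULL,
                       target_censor_prop = NULL, seed = 1L) {
  model <- match.arg(model)
  baseline <- match.arg(baseline)
  censoring <- match.arg(censoring)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (rate <= 0 || shape <= 0 || scale <= 0) {
    stop("'rate', 'shape' and 'scale' must be > 0", call. = FALSE)
  }
  if (!is.null(target_censor_prop)) {
    if (target_censor_prop <= 0 || target_censor_prop >= 1) {
      stop("'target_censor_prop' must lie strictly in (0, 1)",
           call. = FALSE)
    }
    censoring <- "exponential"
  }
  if (censoring == "exponential" && is.null(censor_rate) &&
      is.null(target_censor_prop)) {
    stop("exponential censoring needs 'censor_rate' (or a target ",
         "proportion to calibrate)", call. = FALSE)
  }
  if (!is.null(censor_rate) && censor_rate <= 0) {
    stop("'censor_rate' must be > 0", call. = FALSE)
  }
  if (censoring == "admin") {
    if (is.null(admin_time) || admin_time < 0) {
      stop("administrative censoring needs 'admin_time' >= 0",
           call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), p = length(beta),
                 beta = as.numeric(beta), model = model,
                 baseline = baseline, rate = rate, shape = shape,
                 scale = scale, censoring = censoring,
                 censor_rate = censor_rate, admin_time = admin_time,
                 target_censor_prop = target_censor_prop,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Effective Weibull (shape, scale) of the configured baseline.
.baseline_pars <- function(cfg) {
  if (cfg$baseline == "exponential") {
    list(shape = 1, scale = 1 / cfg$rate)
  } else {
    list(shape = cfg$shape, scale = cfg$scale)
  }
}

# Latent event times by inversion from uniforms u, given lp eta.
.event_times <- function(cfg, u, eta) {
  bp <- .baseline_pars(cfg)
  if (cfg$model == "ph") {
    lambda_w <- bp$scale^(-bp$shape)
    (-log(u) / (lambda_w * exp(eta)))^(1 / bp$shape)
  } else {
    w <- log(-log(u))   # standard Gumbel-minimum by inversion
    exp(log(bp$scale) + eta + w / bp$shape)
  }
}

#' Simulate a right-censored survival task
#'
#' Draws covariates, latent event times and independent censoring
#' times per the [sim_config()], and returns the observed data
#' `T = min(T*, C)`, `delta = 1(T* <= C)` as a [surv_task].  All
#' sampling is by inversion, so the output is a bit-identical,
#' deterministic function of the config (including its seed), and the
#' caller's RNG state is left untouched.
#'
#' The latent truth (uncensored event times, censoring times and the
#' true linear predictor) is attached as `attr(task, "truth")` for
#' oracle checks; [write_task_csv()] does not export it unless the
#' truth columns are added explicitly.
#'
#' @param cfg a [sim_config()].
#' @return A [surv_task] with attribute `"truth"`: a list
#'   `event_time`, `censor_time`, `lp`.
#' @examples
#' task <- simulate_surv(sim_config(n = 100, beta = c(0.5, -0.5),
#'                                  censor_rate = 0.3,
#'                                  censoring = "exponential"))
#' task_summary(task)$censoring_prop
#' @export
simulate_surv <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$censoring == "exponential" && is.null(cfg$censor_rate)) {
    cfg <- calibrate_censoring(cfg)
  }
  with_local_seed(cfg$seed, {
    X <- matrix(stats::rnorm(cfg$n * cfg$p), nrow = cfg$n,
                dimnames = list(NULL, paste0("x", seq_len(cfg$p))))
    eta <- as.vector(X %*% cfg$beta)
    u <- stats::runif(cfg$n)
    t_event <- .event_times(cfg, u, eta)
    t_cens <- switch(cfg$censoring,
      none = rep(Inf, cfg$n),
      exponential = stats::rexp(cfg$n, rate = cfg$censor_rate),
      admin = rep(cfg$admin_time, cfg$n)
    )
    time <- pmin(t_event, t_cens)
    status <- as.integer(t_event <= t_cens)
    task <- surv_task(X, time, status,
                      id = sprintf("sim-%s-%s-n%d-seed%d", cfg$model,
                                   cfg$baseline, cfg$n, cfg$seed))
    attr(task, "truth") <- list(event_time = t_event,
                                censor_time = t_cens, lp = eta)
    task
  })
}

#' Calibrate the exponential censoring rate to a target proportion
#'
#' Solves for the exponential censoring rate whose realized marginal
#' censoring proportion matches `target_censor_prop`, by monotone
#' bisection against a large pilot sample (n = 20000) drawn from the
#' same generative model at a pilot seed derived from `cfg$seed`.  The
#' pilot event times and censoring uniforms are held fixed across rate
#' evaluations, so the realized proportion is a deterministic
#' non-decreasing function of the rate and bisection converges
#' cleanly.
#'
#' @param cfg a [sim_config()] with `target_censor_prop` set.
#' @param pilot_n pilot sample size.
#' @param tol calibration tolerance on the pilot censoring proportion.
#' @param max_iter bisection iteration cap (error on exhaustion).
#' @return The config with `censor_rate` filled in.
#' @export
calibrate_censoring <- function(cfg, pilot_n = 20000L, tol = 0.005,
                                max_iter = 60L) {
  stopifnot(inherits(cfg, "sim_config"))
  target <- cfg$target_censor_prop
  if (is.null(target)) {
    stop("'target_censor_prop' is not set in this config", call. = FALSE)
  }
  pilot_seed <- (cfg$seed + 99991L) %% .Machine$integer.max
  pilot <- with_local_seed(pilot_seed, {
    X <- matrix(stats::rnorm(pilot_n * cfg$p), nrow = pilot_n)
    eta <- as.vector(X %*% cfg$beta)
    list(t_event = .event_times(cfg, stats::runif(pilot_n), eta),
         u_cens = stats::runif(pilot_n))
  })
  realized <- function(rate) {
    mean(-log(pilot$u_cens) / rate < pilot$t_event)
  }
  lo <- 1e-8
  hi <- 1
  it <- 0L
  while (realized(hi) < target) {
    hi <- hi * 4
    it <- it + 1L
    if (it > 60L) stop("censoring calibration failed to bracket target",
                       call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    f <- realized(mid)
    if (abs(f - target) <= tol) {
      cfg$censor_rate <- mid
      return(cfg)
    }
    if (f < target) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "censoring calibration did not converge in %d bisection steps",
    max_iter), call. = FALSE)
}
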
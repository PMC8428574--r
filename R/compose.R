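#' Compose a survival-distribution prediction from lp or crank
#'
#' Turns a linear-predictor (or crank) prediction into a full
#' per-subject survival distribution by deforming a baseline curve
#' `S_0` under one of three model forms.  With `eta_i` the chosen
#' channel value for subject `i`:
#'
#' * `ph` (proportional hazards): `S_i(t) = S_0(t)^{exp(eta_i)}` --
#'   cumulative hazards scale by `exp(eta_i)`; higher `eta` = higher
#'   risk.
#' * `aft` (accelerated failure time):
#'   `S_i(t) = S_0(t * exp(-eta_i))` evaluated under the step-function
#'   convention -- higher `eta` stretches time, i.e. longer survival.
#' * `po` (proportional odds):
#'   `S_i(t) = S_0(t) / (exp(eta_i) + (1 - exp(eta_i)) * S_0(t))`, so
#'   the odds of death `F_i/S_i` equal `exp(eta_i)` times the baseline
#'   odds at every `t`.
#'
#' All three forms return the baseline exactly at `eta = 0`.  Note the
#' direction asymmetry: under `ph`/`po` higher `eta` means higher risk,
#' under `aft` lower risk; a Cox `lp` pairs naturally with `ph`, an AFT
#' `lp` with `aft`.  Composing from `crank` (a pure ranking) is allowed
#' but the resulting distribution is only rank-meaningful, which is
#' flagged with a warning.
#'
#' @param pred a [surv_prediction] carrying the requested channel.
#' @param baseline a single-curve [surv_distribution] for `S_0`, e.g.
#'   from [fit_kaplan_meier()] or [fit_nelson_aalen()].
#' @param form one of `"ph"`, `"aft"`, `"po"`.
#' @param channel one of `"lp"`, `"crank"`.
#' @return A new [surv_prediction] with the `distr` channel replaced by
#'   the composed distribution (other channels preserved).
#' @examples
#' base <- surv_distribution(c(1, 2, 3), c(0.9, 0.5, 0.1))
#' p <- surv_prediction(lp = c(0, log(2)), learner_id = "demo")
#' compose_distr(p, base, form = "ph")$distr$S
#' @export
compose_distr <- function(pred, baseline, form = c("ph", "aft", "po"),
                          channel = c("lp", "crank")) {
  stopifnot(inherits(pred, "surv_prediction"),
            inherits(baseline, "surv_distribution"))
  form <- match.arg(form)
  channel <- match.arg(channel)
  .require_channel(pred, channel, context = sprintf("compose_distr(%s)", form))
  if (nrow(baseline$S) != 1L) {
    stop("'baseline' must hold a single survival curve", call. = FALSE)
  }
  if (channel == "crank") {
    warning("composing from 'crank': the resulting distribution is only ",
            "rank-meaningful", call. = FALSE)
  }
  eta <- pred[[channel]]
  grid <- baseline$grid
  s0 <- as.vector(baseline$S)
  S <- switch(form,
    ph = outer(exp(eta), s0, function(r, s) s^r),
    aft = {
      # S_i(t_k) = S_0(t_k * exp(-eta_i)) under the step convention
      t(vapply(eta, function(e) {
        as.vector(eval_survival(baseline, grid * exp(-e)))
      }, numeric(length(grid))))
    },
    po = {
      r <- exp(eta)
      t(vapply(r, function(ri) s0 / (ri + (1 - ri) * s0),
               numeric(length(grid))))
    }
  )
  if (length(grid) == 1L) S <- matrix(S, ncol = 1L)
  surv_prediction(response = pred$response, crank = pred$crank,
                  lp = pred$lp,
                  distr = surv_distribution(grid, S),
                  learner_id = paste0(pred$learner_id, "+distr(", form, ")"))
}

#' Compose crank (and response) from a distribution prediction
#'
#' Summarizes each predicted survival curve by its restricted mean
#' ([dist_mean()]) or median ([dist_median()]) and sets
#' `crank = -summary` so that shorter predicted survival means higher
#' risk.  The summary is also written to the `response` channel when it
#' is absent or `overwrite_response = TRUE`.
#'
#' @param pred a [surv_prediction] with a `distr` channel.
#' @param summary `"mean"` or `"median"`.
#' @param overwrite_response replace an existing `response` channel.
#' @return A new [surv_prediction] with `crank` (and possibly
#'   `response`) set.
#' @export
compose_crank <- function(pred, summary = c("mean", "median"),
                          overwrite_response = FALSE) {
  stopifnot(inherits(pred, "surv_prediction"))
  summary <- match.arg(summary)
  .require_channel(pred, "distr", context = "compose_crank")
  s <- switch(summary, mean = dist_mean(pred$distr),
              median = dist_median(pred$distr))
  response <- if (is.null(pred$response) || overwrite_response) s
              else pred$response
  surv_prediction(response = response, crank = -s, lp = pred$lp,
                  distr = pred$distr,
                  learner_id = paste0(pred$learner_id, "+crank(", summary, ")"))
}
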
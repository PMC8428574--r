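#' Construct a learner by id
#'
#' The learner contract is the framework's plug-in point: a learner is
#' a list with an `id`, declared `predict_types` (subset of
#' `response`, `crank`, `lp`, `distr`) and a `fit(task)` function
#' returning a model whose `predict(model, X)` method emits a
#' [surv_prediction] populating exactly the declared channels.  Any
#' external model (forests, boosting, neural networks, ...) can be
#' wrapped in the same structure and used throughout [resample()] and
#' [benchmark()].
#'
#' Built-in ids: `"surv.kaplan"`, `"surv.nelson"`, `"surv.coxph"`,
#' `"surv.weibull"`.
#'
#' @param id learner id.
#' @param ... hyper-parameters forwarded to the fit function.
#' @return An object of class `surv_learner`.
#' @examples
#' cox <- lrn("surv.coxph")
#' cox$predict_types
#' @export
lrn <- function(id, ...) {
  hyper <- list(...)
  spec <- switch(id,
    "surv.kaplan" = list(fit = fit_kaplan_meier,
                         predict_types = c("crank", "distr")),
    "surv.nelson" = list(fit = fit_nelson_aalen,
                         predict_types = c("crank", "distr")),
    "surv.coxph" = list(fit = fit_coxph,
                        predict_types = c("lp", "crank", "distr")),
    "surv.weibull" = list(fit = fit_weibull_aft,
                          predict_types = c("response", "lp", "crank",
                                            "distr")),
    stop("unknown learner id: '", id, "'", call. = FALSE)
  )
  new_learner(id, spec$predict_types,
              fit = function(task) do.call(spec$fit, c(list(task), hyper)),
              hyperparams = hyper)
}

#' Build a custom learner object
#'
#' @param id learner id string.
#' @param predict_types channels the learner's predictions populate.
#' @param fit function `task -> model`; the model must have a
#'   `predict(model, X)` method returning a [surv_prediction].
#' @param hyperparams named list recorded for provenance.
#' @return An object of class `surv_learner`.
#' @export
new_learner <- function(id, predict_types, fit, hyperparams = list()) {
  stopifnot(is.character(id), length(predict_types) >= 1L,
            all(predict_types %in% c("response", "crank", "lp", "distr")),
            is.function(fit))
  structure(list(id = id, predict_types = predict_types, fit = fit,
                 hyperparams = hyperparams),
            class = "surv_learner")
}

#' @export
print.surv_learner <- function(x, ...) {
  cat(sprintf("<surv_learner '%s'> predicts: %s\n", x$id,
              paste(x$predict_types, collapse = ", ")))
  invisible(x)
}

#' Distribution-compositor pipeline learner
#'
#' Wraps a learner so that its `lp` (or `crank`) predictions are
#' augmented with a `distr` channel via [compose_distr()]: a baseline
#' survival curve is estimated on the training data by the chosen
#' estimator and deformed per subject under the chosen model form.
#' This is how ranking-only learners become scoreable by
#' distribution measures such as [graf_score()].
#'
#' @param learner a [lrn()] / [new_learner()] object emitting `lp` or
#'   `crank`.
#' @param estimator baseline estimator: `"kaplan"` or `"nelson"`.
#' @param form composition form: `"ph"`, `"aft"` or `"po"`.
#' @param channel channel to compose from; default `"lp"` when the
#'   learner provides it, else `"crank"`.
#' @return A `surv_learner` whose predictions carry `distr`.
#' @export
ppl_distrcompositor <- function(learner, estimator = c("kaplan", "nelson"),
                                form = c("ph", "aft", "po"),
                                channel = NULL) {
  stopifnot(inherits(learner, "surv_learner"))
  estimator <- match.arg(estimator)
  form <- match.arg(form)
  if (is.null(channel)) {
    channel <- if ("lp" %in% learner$predict_types) "lp" else "crank"
  }
  if (!channel %in% learner$predict_types) {
    stop(sprintf("learner '%s' does not emit channel '%s'",
                 learner$id, channel), call. = FALSE)
  }
  base_fit <- switch(estimator, kaplan = fit_kaplan_meier,
                     nelson = fit_nelson_aalen)
  id <- sprintf("%s+distrcompositor(%s,%s)", learner$id, estimator, form)
  new_learner(
    id = id,
    predict_types = union(learner$predict_types, "distr"),
    fit = function(task) {
      inner <- learner$fit(task)
      base_model <- base_fit(task)
      structure(list(inner = inner,
                     baseline = surv_distribution(base_model$grid,
                                                  base_model$surv),
                     form = form, channel = channel, id = id),
                class = c("composed_model", "survkit_model"))
    },
    hyperparams = list(estimator = estimator, form = form,
                       channel = channel)
  )
}

#' @export
predict.composed_model <- function(object, newdata, ...) {
  pred <- stats::predict(object$inner, newdata)
  out <- compose_distr(pred, object$baseline, form = object$form,
                       channel = object$channel)
  out$learner_id <- object$id
  out
}

#' Construct an evaluation measure by id
#'
#' A measure is a specification object: an `id`, the prediction channel
#' it requires (`required_channel`), its optimization `direction`, and
#' a scoring function.  Scoring a prediction that lacks the required
#' channel raises an error before any work is done.  IPCW measures
#' (`needs_G = TRUE`) additionally take a [censoring_weights] object,
#' fitted on the training fold by [resample()] so that evaluation never
#' uses test-fold outcome information.
#'
#' Built-in ids: `"surv.cindex"` (Harrell), `"surv.cindex.uno"`,
#' `"surv.graf"`, `"surv.intlogloss"`, `"surv.schmid"`,
#' `"surv.calib.beta"`, `"surv.calib.km"`, `"surv.auc"` (requires
#' `at_time`; defaults to the median test event time).
#'
#' @param id measure id.
#' @param at_time evaluation horizon for `"surv.auc"`.
#' @return An object of class `surv_measure`.
#' @export
msr <- function(id, at_time = NULL) {
  m <- switch(id,
    "surv.cindex" = list(
      required_channel = "crank", direction = "maximize", needs_G = FALSE,
      fun = function(pred, time, status, G)
        harrell_c(pred$crank, time, status)),
    "surv.cindex.uno" = list(
      required_channel = "crank", direction = "maximize", needs_G = TRUE,
      fun = function(pred, time, status, G)
        uno_c(pred$crank, time, status, G)),
    "surv.graf" = list(
      required_channel = "distr", direction = "minimize", needs_G = TRUE,
      fun = function(pred, time, status, G)
        graf_score(pred$distr, time, status, G)),
    "surv.intlogloss" = list(
      required_channel = "distr", direction = "minimize", needs_G = TRUE,
      fun = function(pred, time, status, G)
        integrated_logloss(pred$distr, time, status, G)),
    "surv.schmid" = list(
      required_channel = "distr", direction = "minimize", needs_G = TRUE,
      fun = function(pred, time, status, G)
        schmid_score(pred$distr, time, status, G)),
    "surv.calib.beta" = list(
      required_channel = "lp", direction = "none", needs_G = FALSE,
      fun = function(pred, time, status, G)
        houwelingen_beta(pred$lp, time, status)),
    "surv.calib.km" = list(
      required_channel = "distr", direction = "minimize", needs_G = FALSE,
      fun = function(pred, time, status, G)
        as.numeric(km_calibration(pred$distr, time, status))),
    "surv.auc" = list(
      required_channel = "crank", direction = "maximize", needs_G = TRUE,
      fun = function(pred, time, status, G) {
        t0 <- if (is.null(at_time)) {
          stats::median(time[status == 1L])
        } else at_time
        uno_auc(pred$crank, time, status, G, t = t0)
      }),
    stop("unknown measure id: '", id, "'", call. = FALSE)
  )
  raw_fun <- m$fun
  m$fun <- function(pred, time, status, G = NULL) {
    .require_channel(pred, m$required_channel,
                     context = sprintf("'%s'", id))
    raw_fun(pred, time, status, G)
  }
  structure(c(list(id = id, at_time = at_time), m),
            class = "surv_measure")
}

#' @export
print.surv_measure <- function(x, ...) {
  cat(sprintf("<surv_measure '%s'> requires: %s (%s)\n", x$id,
              x$required_channel, x$direction))
  invisible(x)
}
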
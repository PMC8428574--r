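#' Typed survival prediction container
#'
#' Every learner returns a `surv_prediction` holding one or more
#' prediction channels for `n` test subjects:
#'
#' * `response` -- a predicted survival time;
#' * `crank` -- a continuous relative-risk ranking, **higher = higher
#'   risk** (shorter predicted survival);
#' * `lp` -- a linear predictor on the model's natural scale
#'   (log-hazard for proportional-hazards models, log-time for
#'   accelerated-failure-time models);
#' * `distr` -- a [surv_distribution] with one curve per subject.
#'
#' At least one channel must be present and all present channels must
#' agree on `n`.  Measures request channels explicitly and scoring a
#' prediction that lacks the required channel is an error, never a
#' silent fallback; use [compose_distr()] / [compose_crank()] to derive
#' missing channels.
#'
#' @param response,crank,lp optional numeric vectors of length `n`.
#' @param distr optional [surv_distribution] with `n` rows.
#' @param learner_id provenance string.
#' @return An object of class `surv_prediction`.
#' @export
surv_prediction <- function(response = NULL, crank = NULL, lp = NULL,
                            distr = NULL, learner_id = "unknown") {
  lens <- c(
    response = if (!is.null(response)) length(response) else NA_integer_,
    crank = if (!is.null(crank)) length(crank) else NA_integer_,
    lp = if (!is.null(lp)) length(lp) else NA_integer_,
    distr = if (!is.null(distr)) nrow(distr$S) else NA_integer_
  )
  present <- lens[!is.na(lens)]
  if (!length(present)) {
    stop("a prediction must carry at least one channel", call. = FALSE)
  }
  n <- unname(present[1L])
  if (any(present != n)) {
    stop("channel lengths disagree: ",
         paste(sprintf("%s = %d", names(present), present), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(crank) && any(!is.finite(crank))) {
    stop("'crank' must be finite", call. = FALSE)
  }
  if (!is.null(distr) && !inherits(distr, "surv_distribution")) {
    stop("'distr' must be a surv_distribution", call. = FALSE)
  }
  structure(list(n = n, response = response, crank = crank, lp = lp,
                 distr = distr, learner_id = learner_id),
            class = "surv_prediction")
}

#' @export
print.surv_prediction <- function(x, ...) {
  chans <- c("response", "crank", "lp", "distr")
  have <- chans[!vapply(x[chans], is.null, logical(1))]
  cat(sprintf("<surv_prediction from '%s'> n = %d, channels: %s\n",
              x$learner_id, x$n, paste(have, collapse = ", ")))
  invisible(x)
}

#' Which channels does a prediction carry?
#' @param pred a `surv_prediction`.
#' @return Character vector, subset of
#'   `c("response", "crank", "lp", "distr")`.
#' @export
pred_channels <- function(pred) {
  chans <- c("response", "crank", "lp", "distr")
  chans[!vapply(pred[chans], is.null, logical(1))]
}

.require_channel <- function(pred, channel, context = "measure") {
  if (is.null(pred[[channel]])) {
    stop(sprintf(
      "prediction from '%s' lacks the '%s' channel required by %s%s",
      pred$learner_id, channel, context,
      if (channel == "distr") " -- wrap the learner with compose_distr()"
      else ""), call. = FALSE)
  }
  invisible(TRUE)
}
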
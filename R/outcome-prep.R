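## Working outcomes: continuous passthrough, binary 0/1, and null-model
## martingale residuals for right-censored survival times.

#' Describe the outcome column(s)
#'
#' @param kind `"continuous"`, `"binary"` or `"survival"`.
#' @param valueColumn column holding the continuous value or binary label.
#' @param positiveLabel label mapped to 1 for binary outcomes.
#' @param timeColumn,eventColumn survival time (positive) and 0/1 event
#'   indicator columns (event = 1 means observed failure).
#' @return an `outcomeSpec` list.
#' @export
outcomeSpec <- function(kind = c("continuous", "binary", "survival"),
                        valueColumn = NULL, positiveLabel = NULL,
                        timeColumn = NULL, eventColumn = NULL) {
  kind <- match.arg(kind)
  if (kind == "survival") {
    if (is.null(timeColumn) || is.null(eventColumn)) {
      stop("survival outcomes need timeColumn and eventColumn")
    }
  } else {
    if (is.null(valueColumn)) stop(kind, " outcomes need valueColumn")
    if (kind == "binary" && is.null(positiveLabel)) {
      stop("binary outcomes need positiveLabel")
    }
  }
  structure(list(kind = kind, valueColumn = valueColumn,
                 positiveLabel = positiveLabel, timeColumn = timeColumn,
                 eventColumn = eventColumn), class = "outcomeSpec")
}

#' @rdname outcomeSpec
#' @param spec an `outcomeSpec`.
#' @export
outcomeColumns <- function(spec) {
  if (spec$kind == "survival") c(spec$timeColumn, spec$eventColumn)
  else spec$valueColumn
}

.checkSurv <- function(times, events) {
  times <- as.numeric(times); events <- as.numeric(events)
  if (length(times) != length(events)) stop("times and events lengths differ")
  if (length(times) < 2L) stop("need n >= 2 survival observations")
  if (any(times <= 0)) stop("survival times must be positive")
  if (!all(events %in% c(0, 1))) stop("event indicator must be 0/1")
  list(times = times, events = events)
}

#' Nelson-Aalen cumulative hazard of the null model
#'
#' Cumulative hazard of a covariate-free model,
#' \eqn{\hat\Lambda(t) = \sum_{t_j \le t} d_j / n_j} over the distinct
#' event times, with censored observations tied with an event counted in
#' the risk set at that time. Computed through
#' [survival::survfit()] with `ctype = 1`.
#'
#' @param times positive observation times.
#' @param events 0/1 event indicators.
#' @return a [CumulativeHazard-class].
#' @examples
#' nelsonAalen(c(1, 2, 3), c(1, 1, 1))  # 1/3, 5/6, 11/6
#' @export
nelsonAalen <- function(times, events) {
  s <- .checkSurv(times, events)
  if (sum(s$events) == 0) {
    return(methods::new("CumulativeHazard", eventTimes = numeric(0),
                        hazard = numeric(0)))
  }
  sf <- survival::survfit(survival::Surv(s$times, s$events) ~ 1, ctype = 1)
  keep <- sf$n.event > 0
  methods::new("CumulativeHazard", eventTimes = sf$time[keep],
               hazard = sf$cumhaz[keep])
}

#' Evaluate a cumulative hazard at arbitrary times
#'
#' Right-continuous step-function evaluation, \eqn{\hat\Lambda(0) = 0}.
#'
#' @param hazard a [CumulativeHazard-class].
#' @param times numeric evaluation times.
#' @return numeric vector.
#' @export
evaluateHazard <- function(hazard, times) {
  if (!length(hazard@eventTimes)) return(rep(0, length(times)))
  sf <- stats::stepfun(hazard@eventTimes, c(0, hazard@hazard))
  sf(times)
}

#' Null-model martingale residuals
#'
#' \eqn{M_i = \delta_i - \hat\Lambda(t_i)} with the Nelson-Aalen null-model
#' cumulative hazard; residuals lie in \eqn{(-\infty, 1]} and sum to zero.
#' This is the working response the causal regression uses for
#' right-censored outcomes.
#'
#' @inheritParams nelsonAalen
#' @return a [WorkingResponse-class] of kind `"survival"`.
#' @export
martingaleResiduals <- function(times, events) {
  s <- .checkSurv(times, events)
  lam <- evaluateHazard(nelsonAalen(s$times, s$events), s$times)
  methods::new("WorkingResponse", y = s$events - lam, kind = "survival",
               provenance = "null-model martingale residual (Nelson-Aalen)")
}

#' Build the working response from a clinical table
#'
#' Dispatches on the outcome kind: continuous values pass through, binary
#' labels map to 0/1 (`positiveLabel` = 1), right-censored survival times
#' become null-model martingale residuals. Unordered categorical outcomes
#' with more than two levels are rejected.
#'
#' @param clinical data.frame (already complete-case filtered).
#' @param spec an [outcomeSpec()].
#' @return a [WorkingResponse-class].
#' @export
prepareOutcome <- function(clinical, spec) {
  stopifnot(inherits(spec, "outcomeSpec"))
  cols <- outcomeColumns(spec)
  miss <- setdiff(cols, names(clinical))
  if (length(miss)) stop("outcome column(s) missing: ", paste(miss, collapse = ", "))
  if (anyNA(clinical[, cols])) stop("outcome columns contain missing values")
  switch(spec$kind,
    continuous = {
      y <- as.numeric(clinical[[spec$valueColumn]])
      methods::new("WorkingResponse", y = y, kind = "continuous",
                   provenance = paste0("continuous '", spec$valueColumn, "'"))
    },
    binary = {
      x <- as.character(clinical[[spec$valueColumn]])
      lev <- unique(x)
      if (length(lev) > 2L) {
        stop("binary outcome column '", spec$valueColumn, "' has ",
             length(lev), " observed values")
      }
      if (!spec$positiveLabel %in% lev) {
        warning("positive label '", spec$positiveLabel,
                "' not observed; all responses coded 0")
      }
      methods::new("WorkingResponse",
                   y = as.numeric(x == spec$positiveLabel), kind = "binary",
                   provenance = paste0("binary '", spec$valueColumn,
                                       "', 1 = ", spec$positiveLabel))
    },
    survival = martingaleResiduals(clinical[[spec$timeColumn]],
                                   clinical[[spec$eventColumn]])
  )
}
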
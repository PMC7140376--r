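#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator of the survival function under right
#' censoring. At each distinct time with at least one event, the estimate is
#' multiplied by (1 - d/n) where d is the number of deaths at that time and n
#' the number at risk just before it. Deaths are processed before censorings
#' at tied times (the standard convention), so subjects censored at an event
#' time still count as at risk for that event.
#'
#' @param times non-negative follow-up times in days.
#' @param events 0/1 event indicators (1 = death observed, 0 = censored).
#' @return an object of class `km_curve` with fields `event_times`, `at_risk`,
#'   `events`, `survival` (estimate just after each event time), `n` (subjects
#'   at entry) and `max_followup`.
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.numeric(events)
  if (!length(times)) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events))
    stop("`times` and `events` must have equal length", call. = FALSE)
  if (anyNA(times) || anyNA(events))
    stop("missing values in survival input", call. = FALSE)
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(events %in% c(0, 1)))
    stop("`events` must be 0 or 1", call. = FALSE)
  tau <- sort(unique(times[events == 1]))
  at_risk <- vapply(tau, function(t) sum(times >= t), numeric(1))
  d <- vapply(tau, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - d / at_risk)
  structure(list(event_times = tau, at_risk = at_risk, events = d,
                 survival = surv, n = length(times),
                 max_followup = max(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d distinct event times, max follow-up %g days\n",
              x$n, length(x$event_times), x$max_followup))
  if (length(x$event_times)) {
    df <- data.frame(time = x$event_times, at_risk = x$at_risk,
                     events = x$events, survival = round(x$survival, 4))
    print(utils::head(df, 10), row.names = FALSE)
    if (length(x$event_times) > 10) cat("  ...\n")
  } else {
    cat("  (no events observed; survival is 1 throughout follow-up)\n")
  }
  invisible(x)
}

#' Median survival with "not reached" semantics
#'
#' The median is the smallest event time at which the survival estimate falls
#' to 0.5 or below. If the curve never reaches 0.5 within follow-up the median
#' is not reached and only a lower bound -- the group's maximum follow-up --
#' can be reported; such groups are rendered `"> M days"`.
#'
#' @param curve a `km_curve`.
#' @return an object of class `km_median` with fields `reached`, `value_days`
#'   (if reached) and `lower_bound_days` (if not).
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- which(curve$survival <= 0.5)
  if (length(idx)) {
    structure(list(reached = TRUE, value_days = curve$event_times[idx[1L]],
                   lower_bound_days = NULL), class = "km_median")
  } else {
    structure(list(reached = FALSE, value_days = NULL,
                   lower_bound_days = curve$max_followup), class = "km_median")
  }
}

#' @export
format.km_median <- function(x, ...) {
  if (x$reached) paste0(format(x$value_days, trim = TRUE), " days")
  else paste0("> ", format(x$lower_bound_days, trim = TRUE), " days")
}

#' @export
print.km_median <- function(x, ...) {
  cat("Median survival:", format(x), "\n")
  invisible(x)
}

# effective median used for between-extreme gap comparisons: the estimate if
# reached, otherwise its lower bound (max follow-up)
.median_value <- function(m) if (m$reached) m$value_days else m$lower_bound_days

#' Export a KM curve as a step table
#' @param curve a `km_curve`.
#' @return data.frame with columns time, at_risk, events, survival.
#' @export
km_table <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  data.frame(time = curve$event_times, at_risk = curve$at_risk,
             events = curve$events, survival = curve$survival)
}

#' Plot one or more KM curves as step functions
#'
#' @param x a `km_curve` or list of them (optionally named).
#' @param col line colors.
#' @param xlab,ylab,main usual graphics parameters.
#' @param ... passed to [graphics::plot()].
#' @export
plot.km_curve <- function(x, col = "black", xlab = "Days",
                          ylab = "Survival probability", main = NULL, ...) {
  plot_km(list(x), col = col, xlab = xlab, ylab = ylab, main = main, ...)
}

#' @rdname plot.km_curve
#' @param curves list of `km_curve` objects.
#' @export
plot_km <- function(curves, col = NULL, xlab = "Days",
                    ylab = "Survival probability", main = NULL, ...) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  if (is.null(col)) col <- seq_along(curves)
  xmax <- max(vapply(curves, function(c) c$max_followup, numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, main = main, ...)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    tt <- c(0, cv$event_times, cv$max_followup)
    ss <- c(1, cv$survival, if (length(cv$survival)) cv$survival[length(cv$survival)] else 1)
    graphics::lines(stats::stepfun(tt[-1], ss), do.points = FALSE,
                    col = col[(i - 1) %% length(col) + 1])
  }
  if (!is.null(names(curves)))
    graphics::legend("bottomleft", legend = names(curves), col = col, lty = 1,
                     bty = "n", cex = 0.8)
  invisible(curves)
}
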
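#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator computed from first principles. At each distinct
#' event time \eqn{t_i} with \eqn{d_i} events among \eqn{n_i} at risk,
#' \deqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i).}
#' Ties follow the standard convention that events precede censorings at the
#' same time (a record censored at \eqn{t_i} is still at risk for the events
#' at \eqn{t_i}). The median is the first event time with \eqn{S(t) \le 0.5};
#' if the curve never crosses 0.5 the median is "not reached" (NA).
#'
#' @param time Positive follow-up times (e.g. months).
#' @param event 1 = event observed, 0 = censored.
#' @return Object of class \code{"kmEstimate"}: list with \code{table}
#'   (data.frame time, n_risk, n_event, n_censor, surv over distinct event
#'   times), \code{median}, \code{n}, \code{nEvents}.
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' km$table$surv  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  eventTimes <- sort(unique(time[event == 1]))
  if (length(eventTimes) == 0L) {
    tab <- data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), n_censor = integer(),
                      surv = numeric())
    return(structure(list(table = tab, median = NA_real_,
                          n = length(time), nEvents = 0L),
                     class = "kmEstimate"))
  }
  nRisk <- vapply(eventTimes, function(t) sum(time >= t), integer(1))
  nEvent <- vapply(eventTimes, function(t) sum(time == t & event == 1),
                   integer(1))
  nCensor <- vapply(eventTimes, function(t) sum(time == t & event == 0),
                    integer(1))
  surv <- cumprod(1 - nEvent / nRisk)
  med <- eventTimes[which(surv <= 0.5)[1]]
  if (length(med) == 0L || is.na(med)) med <- NA_real_
  structure(list(table = data.frame(time = eventTimes, n_risk = nRisk,
                                    n_event = nEvent, n_censor = nCensor,
                                    surv = surv),
                 median = med, n = length(time), nEvents = sum(event == 1)),
            class = "kmEstimate")
}

#' @export
print.kmEstimate <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,", x$nEvents, "events\n")
  cat("  median survival:",
      if (is.na(x$median)) "not reached" else format(x$median), "\n")
  if (nrow(x$table)) print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Two-sample log-rank (Mantel-Haenszel) test
#'
#' At each distinct event time a 2x2 table of events by stratum is formed;
#' the observed minus hypergeometric-expected events in the first stratum are
#' summed and scaled by the summed hypergeometric variance:
#' \deqn{\chi^2 = (\sum O_1 - \sum E_1)^2 / \sum V, \quad df = 1.}
#'
#' @param time Positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param stratum Two-level grouping vector.
#' @return Object of class \code{"htest"} with the chi-square statistic, df,
#'   p-value and per-stratum observed/expected event counts.
#' @export
logrankTest <- function(time, event, stratum) {
  stopifnot(length(time) == length(event), length(time) == length(stratum))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite", call. = FALSE)
  stratum <- factor(stratum)
  stratum <- droplevels(stratum)
  if (nlevels(stratum) != 2L)
    stop("log-rank test requires exactly 2 strata (have ",
         nlevels(stratum), ")", call. = FALSE)
  byStrat <- tapply(event, stratum, sum)
  if (any(byStrat == 0))
    warning("stratum with zero events: ",
            paste(names(byStrat)[byStrat == 0], collapse = ", "),
            call. = FALSE)
  g1 <- stratum == levels(stratum)[1]
  eventTimes <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  structure(
    list(statistic = c(`chi-square` = chisq),
         parameter = c(df = 1),
         p.value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
         method = "Two-sample log-rank (Mantel-Haenszel) test",
         data.name = paste("strata:", paste(levels(stratum),
                                            collapse = " vs ")),
         observed = stats::setNames(c(O, sum(event) - O), levels(stratum)),
         expected = stats::setNames(c(E, sum(event) - E), levels(stratum))),
    class = "htest")
}

#' Attach index-based strata to survival records
#'
#' @param scores [scoreSamples()] output (sample_id, fourteen_q_index, call).
#' @param surv data.frame: sample_id, time, event.
#' @param mode "call" (use the defect call), "threshold" (re-threshold the
#'   index) or "tertile" (index tertiles T1 < T2 < T3).
#' @param threshold Threshold for "threshold" mode (default 8.5, which makes
#'   it coincide with "call" mode under the default classifier).
#' @return \code{surv} restricted to joinable samples, with a \code{stratum}
#'   column; attribute \code{nUnmatched} counts join losses.
#' @export
stratifyByIndex <- function(scores, surv,
                            mode = c("call", "threshold", "tertile"),
                            threshold = 8.5) {
  mode <- match.arg(mode)
  stopifnot(all(c("sample_id", "time", "event") %in% names(surv)),
            all(c("sample_id", "fourteen_q_index") %in% names(scores)))
  x <- merge(surv, scores[, c("sample_id", "fourteen_q_index",
                              intersect("call", names(scores)))],
             by = "sample_id", sort = FALSE)
  if (nrow(x) == 0L)
    stop("no samples shared between scores and survival table",
         call. = FALSE)
  nUnmatched <- nrow(surv) - nrow(x)
  if (nUnmatched > 0)
    message(nUnmatched, " survival record(s) without a score were dropped")
  x$stratum <- switch(mode,
    call = {
      if (!"call" %in% names(x)) stop("scores lack a call column",
                                      call. = FALSE)
      ifelse(x$call == "positive", "14q-I(+)", "14q-I(-)")
    },
    threshold = ifelse(x$fourteen_q_index > threshold,
                       "14q-I(+)", "14q-I(-)"),
    tertile = {
      q <- stats::quantile(x$fourteen_q_index, c(1, 2) / 3, names = FALSE)
      cut(x$fourteen_q_index, breaks = c(-Inf, q, Inf),
          labels = c("T1", "T2", "T3"))
    })
  x$stratum <- as.character(x$stratum)
  out <- x[, c("sample_id", "time", "event", "stratum")]
  attr(out, "nUnmatched") <- nUnmatched
  out
}

#' Per-stratum Kaplan-Meier curves plus a log-rank comparison
#'
#' Convenience wrapper: estimates a KM curve per stratum and, when exactly
#' two strata are present, runs the log-rank test. A single stratum is an
#' error (no contrast to test).
#'
#' @param strat Output of [stratifyByIndex()].
#' @return List: \code{curves} (named list of kmEstimate), \code{test}
#'   (htest or NULL when > 2 strata).
#' @export
survivalByStratum <- function(strat) {
  stopifnot(all(c("time", "event", "stratum") %in% names(strat)))
  strata <- unique(strat$stratum)
  if (length(strata) < 2L)
    stop("only one stratum ('", strata, "'); nothing to compare",
         call. = FALSE)
  curves <- lapply(split(strat, strat$stratum),
                   function(d) kmEstimate(d$time, d$event))
  test <- if (length(strata) == 2L)
    logrankTest(strat$time, strat$event, strat$stratum)
  else NULL
  list(curves = curves, test = test)
}
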
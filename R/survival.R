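#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator via \pkg{survival}'s
#' \code{survfit} and returns it as a validated
#' \code{\linkS4class{KMCurve}}. Ties between events and censorings at
#' the same time follow the classical convention: events precede
#' censoring, so censored subjects at time t are still at risk for the
#' event at t.
#'
#' @param times positive observation times (days).
#' @param events 0/1 event indicators (0 = right-censored).
#' @return a \code{\linkS4class{KMCurve}}.
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(0, 1, 1))
#' survivalAt(km, 2)  # 0.5
#' @importFrom survival survfit Surv
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (length(times) != length(events))
    stop("times and events must have equal length", call. = FALSE)
  if (any(!is.finite(times) | times <= 0))
    stop("times must be positive and finite", call. = FALSE)
  if (any(!events %in% c(0, 1)))
    stop("events must be 0 or 1", call. = FALSE)
  fit <- survfit(Surv(times, events) ~ 1, conf.type = "none")
  new("KMCurve", time = as.numeric(fit$time), surv = as.numeric(fit$surv),
      nRisk = as.numeric(fit$n.risk), nEvent = as.numeric(fit$n.event),
      nCensor = as.numeric(fit$n.censor), n = length(times))
}

#' Survival probability at a time point
#' @param curve a \code{\linkS4class{KMCurve}}.
#' @param t time (days); the step function is right-continuous, so the
#'   value at an event time is the post-event probability.
#' @return S(t) in [0, 1].
#' @export
survivalAt <- function(curve, t) {
  stopifnot(is(curve, "KMCurve"))
  idx <- sum(curve@time <= t)
  if (idx == 0L) 1 else curve@surv[idx]
}

#' Median survival time
#'
#' Smallest observed time at which the survival curve reaches 0.5 or
#' below; \code{NA} when the curve never does.
#'
#' @param curve a \code{\linkS4class{KMCurve}}.
#' @return time in days, or \code{NA_real_} when undefined.
#' @export
medianSurvival <- function(curve) {
  stopifnot(is(curve, "KMCurve"))
  hit <- which(curve@surv <= 0.5 + 1e-12)
  if (length(hit) == 0L) NA_real_ else curve@time[hit[1L]]
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' event times (hypergeometric variance), chi-square with 1 df, computed
#' via \pkg{survival}'s \code{survdiff}. When neither group has any
#' event the test is undefined; a chi-square of 0 with p = 1 is returned
#' with a warning.
#'
#' @param timesA,eventsA times and 0/1 event flags of group A.
#' @param timesB,eventsB times and 0/1 event flags of group B.
#' @return list with \code{chisq}, \code{df} and \code{p}.
#' @importFrom survival survdiff Surv
#' @importFrom stats pchisq
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0L || length(timesB) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  if (sum(eventsA) + sum(eventsB) == 0) {
    warning("no events in either group; log-rank undefined, returning p = 1")
    return(list(chisq = 0, df = 1L, p = 1))
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  group <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survdiff(Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq), df = 1L,
       p = unname(pchisq(sd$chisq, df = 1, lower.tail = FALSE)))
}

#' Fixed-horizon lesion incidence
#'
#' Estimates the cumulative incidence of lesion onset by day \code{t} for
#' one genotype. \code{method = "crude"} is the simple proportion among
#' subjects whose lesion status at \code{t} is known (event by \code{t},
#' or lesion-free follow-up through \code{t}); \code{method = "km"} is
#' one minus the Kaplan-Meier lesion-free survival at \code{t}, which
#' uses partially followed subjects as well.
#'
#' @param cohort a cohort \code{data.frame} (see
#'   \code{\link{simulateCohort}} for the column contract).
#' @param genotype one of \code{"WT"}, \code{"SIRT2KO"}, \code{"SOD1KO"},
#'   \code{"DKO"}.
#' @param t horizon in days.
#' @param method \code{"crude"} (default) or \code{"km"}.
#' @return list with \code{incidence}, \code{n} (subjects contributing),
#'   \code{genotype}, \code{t} and \code{method}. \code{incidence} is
#'   \code{NA} when no subject is informative.
#' @export
incidenceAt <- function(cohort, genotype, t, method = c("crude", "km")) {
  method <- match.arg(method)
  validateCohort(cohort)
  sub <- cohort[cohort$genotype == genotype, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no subjects of genotype ", genotype, call. = FALSE)
  if (method == "crude") {
    evt <- sub$lesion_event == 1 & sub$lesion_time <= t
    known <- evt | sub$lesion_time >= t
    n <- sum(known)
    if (n == 0L) {
      warning("all subjects censored before day ", t,
              "; crude incidence undefined")
      return(list(incidence = NA_real_, n = 0L, genotype = genotype,
                  t = t, method = method))
    }
    list(incidence = sum(evt) / n, n = n, genotype = genotype, t = t,
         method = method)
  } else {
    km <- kmEstimate(sub$lesion_time, sub$lesion_event)
    list(incidence = 1 - survivalAt(km, t), n = nrow(sub),
         genotype = genotype, t = t, method = method)
  }
}

#' Percent reduction relative to a reference
#'
#' \code{100 * (reference - test) / reference}, rounded to one decimal —
#' the arithmetic behind statements like a median lifespan of 65 weeks
#' being 21.7 % shorter than a reference of 83 weeks.
#'
#' @param reference reference value (> 0), e.g. median lifespan in weeks.
#' @param test test value on the same scale.
#' @return percent reduction, one decimal.
#' @examples
#' percentReduction(83, 65)  # 21.7
#' @export
percentReduction <- function(reference, test) {
  if (!is.finite(reference) || reference <= 0)
    stop("reference must be positive", call. = FALSE)
  round(100 * (reference - test) / reference, 1)
}
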
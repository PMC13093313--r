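## Thermal-tolerance phenotype scoring: Kaplan-Meier survival, LT50,
## Fleming-Harrington G^rho group tests, and allometric standardization of
## respiration rates.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate over distinct event times; individuals censored
#' at t remain at risk at t (standard convention). Backed by
#' [survival::survfit()].
#'
#' @param time positive event/censoring times.
#' @param event 1 = death observed, 0 = censored.
#' @param group optional label attached to the curve.
#' @return data.frame of class `kmCurve`: time, n_risk, n_event, surv,
#'   with the group label in `attr(, "group")`.
#' @export
kaplanMeier <- function(time, event, group = NA_character_) {
  if (!length(time)) pnStop("inputError", "no records")
  if (any(time <= 0)) pnStop("inputError", "times must be positive")
  if (!all(event %in% c(0, 1))) pnStop("inputError", "event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  attr(out, "group") <- group
  class(out) <- c("kmCurve", "data.frame")
  out
}

#' Time at which survival first reaches 50%
#'
#' Smallest event time with S(t) <= 0.5 on the Kaplan-Meier step function;
#' `NA` (not reached) when survival never drops that far. With time
#' measured from the onset of a lethal challenge this is the LT50.
#'
#' @param curve a [kaplanMeier()] curve.
#' @return the LT50 time, or `NA_real_` when not reached.
#' @export
lt50 <- function(curve) {
  hit <- which(curve$n_event > 0 & curve$surv <= 0.5)
  if (!length(hit)) return(NA_real_)
  curve$time[hit[1]]
}

#' Fleming-Harrington G^rho test between survival groups
#'
#' Weights observed-minus-expected death counts by pooled KM survival
#' S(t-)^rho: rho = 0 is the log-rank test, rho = 1 the
#' Peto-Prentice/Wilcoxon-type test for crossing curves. Backed by
#' [survival::survdiff()]; optional stratification (e.g. by tank) sums
#' O - E within strata.
#'
#' @param time,event,group parallel vectors over individuals.
#' @param rho 0 (log-rank) or 1 (Wilcoxon-type).
#' @param strata optional stratification factor.
#' @return list(statistic, df, p_value).
#' @export
grhoTest <- function(time, event, group, rho = 0, strata = NULL) {
  if (length(unique(group)) < 2) pnStop("inputError", "need >= 2 groups")
  if (sum(event) < 1) pnStop("inputError", "need >= 1 event")
  df <- data.frame(time = time, event = event, group = group)
  if (is.null(strata)) {
    fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                              data = df, rho = rho)
  } else {
    df$str <- strata
    fit <- survival::survdiff(
      survival::Surv(time, event) ~ group + survival::strata(str),
      data = df, rho = rho)
  }
  k <- length(unique(group)) - 1L
  list(statistic = fit$chisq, df = k,
       p_value = pchisq(fit$chisq, k, lower.tail = FALSE))
}

#' Choose rho from whether two curves cross
#'
#' Evaluates both step functions at the union of their event times; a
#' strict sign change of S1(t) - S2(t) (zeros ignored) selects the
#' Wilcoxon-type test (rho = 1), otherwise the log-rank test (rho = 0).
#'
#' @param curve1,curve2 curves from [kaplanMeier()].
#' @return 0 or 1.
#' @export
crossingRule <- function(curve1, curve2) {
  times <- sort(unique(c(curve1$time, curve2$time)))
  stepS <- function(curve, t) {
    vapply(t, function(tt) {
      i <- which(curve$time <= tt)
      if (!length(i)) 1 else curve$surv[max(i)]
    }, numeric(1))
  }
  d <- stepS(curve1, times) - stepS(curve2, times)
  s <- sign(d[d != 0])
  if (length(s) >= 2 && any(diff(s) != 0)) 1 else 0
}

#' Allometric correction of a metabolic rate
#'
#' Standardizes a measured rate to a reference dry weight:
#' `Ys = (Ws / We)^b * Ye`, with standard weight Ws = 1 g and allometric
#' exponent b = 0.75 by default.
#'
#' @param Ye measured rate (mg O2 h^-1).
#' @param We measured dry weight (g, > 0).
#' @param Ws standard weight (g, default 1).
#' @param b allometric exponent (default 0.75).
#' @return corrected rate Ys, same unit as Ye.
#' @export
allometricCorrection <- function(Ye, We, Ws = 1, b = 0.75) {
  if (any(We <= 0) || any(Ws <= 0)) pnStop("inputError", "weights must be > 0")
  (Ws / We)^b * Ye
}
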
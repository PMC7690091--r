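#' Kaplan-Meier product-limit estimator
#'
#' Thin wrapper around [survival::survfit()] returning the step function in
#' a tabular form convenient for round-trip checks against digitized
#' coordinates. Ties between events and censorings at the same time follow
#' the standard convention: events are processed first, so tied censored
#' subjects are still in the risk set at that time.
#'
#' @param ipd A data frame with columns `time` and `event`.
#' @return A `ptcl_km` object: list with `table` (columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`) and `n` (sample size).
#' @export
km_estimator <- function(ipd) {
  stopifnot(nrow(ipd) > 0)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(ipd), conf.type = "none")
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    survival = sf$surv)
  structure(list(table = tab, n = nrow(ipd)), class = "ptcl_km")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km A `ptcl_km` object.
#' @param t Time(s) in weeks.
#' @return S(t), right-continuous step evaluation (S = 1 before the first
#'   event).
#' @export
km_survival_at <- function(km, t) {
  tab <- km$table
  idx <- findInterval(t, tab$time)
  c(1, tab$survival)[idx + 1]
}

#' Median survival of a step function
#'
#' Smallest time at which the survival estimate drops to 0.5 or below. When
#' the curve never reaches 0.5 the median is undefined and flagged as such
#' (never encoded as a sentinel value).
#'
#' @param km A `ptcl_km` object (or a `ptcl_survfit`, for which the
#'   parametric median is returned with `defined = is.finite(median)`).
#' @return List with elements `weeks` (numeric or `NA`) and `defined`
#'   (logical).
#' @export
median_survival <- function(km) {
  if (inherits(km, "ptcl_survfit")) {
    m <- fit_quantile(km, 0.5)
    return(list(weeks = if (is.finite(m)) m else NA_real_,
                defined = is.finite(m)))
  }
  tab <- km$table
  hit <- which(tab$survival <= 0.5)
  if (length(hit) == 0) return(list(weeks = NA_real_, defined = FALSE))
  list(weeks = tab$time[min(hit)], defined = TRUE)
}

#' Cox proportional-hazards comparison of two arms
#'
#' Fits a two-arm Cox model (Breslow tie handling) and reports the hazard
#' ratio of arm A versus arm B with its Wald 95% confidence interval.
#'
#' @param ipd_a,ipd_b IPD data frames (`time`, `event`) for the two arms.
#' @return List with `hr`, `ci_low`, `ci_high`, `log_hr`, `se_log_hr`.
#' @export
cox_hr <- function(ipd_a, ipd_b) {
  stopifnot(nrow(ipd_a) > 0, nrow(ipd_b) > 0)
  if (sum(ipd_a$event) + sum(ipd_b$event) == 0)
    stop("no events in either arm")
  d <- rbind(
    data.frame(time = ipd_a$time, event = ipd_a$event, grp = 1),
    data.frame(time = ipd_b$time, event = ipd_b$event, grp = 0)
  )
  fit <- survival::coxph(survival::Surv(time, event) ~ grp, data = d,
                         ties = "breslow")
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(hr = exp(b), ci_low = exp(b - 1.959964 * se),
       ci_high = exp(b + 1.959964 * se), log_hr = b, se_log_hr = se)
}

#' Proportional-hazards goodness-of-fit test
#'
#' Grambsch-Therneau test on the scaled Schoenfeld residuals of the arm
#' covariate ([survival::cox.zph()]); the proportional-hazards assumption is
#' rejected when p < `alpha`.
#'
#' @param ipd_a,ipd_b IPD data frames for the two arms.
#' @param alpha Rejection level (default 0.05).
#' @return List with `p_value` and `reject_ph` (logical).
#' @export
ph_test <- function(ipd_a, ipd_b, alpha = 0.05) {
  stopifnot(nrow(ipd_a) > 0, nrow(ipd_b) > 0)
  d <- rbind(
    data.frame(time = ipd_a$time, event = ipd_a$event, grp = 1),
    data.frame(time = ipd_b$time, event = ipd_b$event, grp = 0)
  )
  fit <- survival::coxph(survival::Surv(time, event) ~ grp, data = d,
                         ties = "breslow")
  z <- survival::cox.zph(fit)
  p <- z$table["grp", "p"]
  list(p_value = unname(p), reject_ph = unname(p) < alpha)
}
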
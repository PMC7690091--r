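#' Candidate parametric survival families
#'
#' The six families considered for overall-survival extrapolation:
#' exponential, Weibull, Gompertz, log-logistic, log-normal and generalized
#' gamma (Prentice mu/sigma/Q parameterization, which nests Weibull,
#' log-normal and gamma).
#'
#' @return Character vector of family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gompertz", "loglogistic", "lognormal", "gengamma")
}

# family -> flexsurv distribution suffix and parameter names
.family_info <- function(family) {
  switch(family,
    exponential = list(dist = "exp",      pars = "rate"),
    weibull     = list(dist = "weibull",  pars = c("shape", "scale")),
    gompertz    = list(dist = "gompertz", pars = c("shape", "rate")),
    loglogistic = list(dist = "llogis",   pars = c("shape", "scale")),
    lognormal   = list(dist = "lnorm",    pars = c("meanlog", "sdlog")),
    gengamma    = list(dist = "gengamma", pars = c("mu", "sigma", "Q")),
    stop("unknown survival family: ", family)
  )
}

.check_params <- function(family, params) {
  info <- .family_info(family)
  if (length(params) != length(info$pars))
    stop(family, " expects ", length(info$pars), " parameters (",
         paste(info$pars, collapse = ", "), ")")
  params <- stats::setNames(as.numeric(params), info$pars)
  pos <- switch(family,
    exponential = "rate", weibull = c("shape", "scale"),
    gompertz = "rate", loglogistic = c("shape", "scale"),
    lognormal = "sdlog", gengamma = "sigma")
  if (any(!is.finite(params))) stop("non-finite parameter for ", family)
  if (any(params[pos] <= 0))
    stop("parameter(s) ", paste(pos[params[pos] <= 0], collapse = ", "),
         " must be positive for ", family)
  params
}

.dist_fun <- function(prefix, family) {
  get(paste0(prefix, .family_info(family)$dist), envir = asNamespace("flexsurv"),
      inherits = TRUE)
}

#' Evaluate a parametric survival function
#'
#' Closed-form S(t) for any of the six candidate families. The Gompertz
#' survival is `exp(-(b/a) (e^{a t} - 1))`; a negative shape `a` gives a
#' defective (plateauing) curve and `a = 0` reduces to the exponential.
#'
#' @param fit A `ptcl_survfit` object from [fit_parametric()], or a family
#'   name (then `params` must be given).
#' @param t Time(s) in weeks, `t >= 0`.
#' @param params Parameter vector in the family's canonical order (see
#'   [surv_families()]); ignored when `fit` is a fit object.
#' @return Survival probability/ies in \[0, 1\].
#' @examples
#' survival_at("exponential", 13.8629, params = 0.05)  # ~0.5
#' @export
survival_at <- function(fit, t, params = NULL) {
  if (inherits(fit, "ptcl_survfit")) {
    family <- fit$family; params <- fit$params
  } else {
    family <- fit
  }
  stopifnot(all(t >= 0))
  params <- .check_params(family, params)
  pfun <- .dist_fun("p", family)
  args <- c(list(q = t), as.list(params), list(lower.tail = FALSE))
  as.numeric(do.call(pfun, args))
}

#' Median (or any quantile) of a fitted parametric curve
#'
#' @param fit A `ptcl_survfit` object or family name.
#' @param p Survival probability at which to invert (default 0.5, the
#'   median).
#' @param params Parameter vector when `fit` is a family name.
#' @return Time in weeks at which S(t) = p; `Inf` for defective curves whose
#'   plateau lies above `p`.
#' @export
fit_quantile <- function(fit, p = 0.5, params = NULL) {
  if (inherits(fit, "ptcl_survfit")) {
    family <- fit$family; params <- fit$params
  } else {
    family <- fit
  }
  params <- .check_params(family, params)
  if (family == "gompertz" && params[["shape"]] < 0) {
    plateau <- exp(params[["rate"]] / params[["shape"]])
    if (plateau >= p) return(Inf)
  }
  qfun <- .dist_fun("q", family)
  as.numeric(do.call(qfun, c(list(p = 1 - p), as.list(params))))
}

#' Weekly death probability from a survival curve
#'
#' Converts a parametric survival curve into the per-cycle transition
#' probability to death used by the Markov engine:
#' `p(w) = 1 - S(w + 1) / S(w)` for week index `w >= 0`. When the curve is
#' exhausted (`S(w) = 0`) the probability is 1, with a warning.
#'
#' @param fit A `ptcl_survfit` object or family name.
#' @param week_index Integer week index/indices (0-based).
#' @param params Parameter vector when `fit` is a family name.
#' @return Probability/ies in \[0, 1\].
#' @export
weekly_death_prob <- function(fit, week_index, params = NULL) {
  stopifnot(all(week_index >= 0))
  s0 <- survival_at(fit, week_index, params = params)
  s1 <- survival_at(fit, week_index + 1, params = params)
  p <- ifelse(s0 > 0, 1 - s1 / s0, 1)
  if (any(s0 == 0))
    warning("survival exhausted (S = 0) at some requested weeks; returning 1")
  pmin(pmax(p, 0), 1)
}

#' Per-cycle death probabilities for a whole horizon
#'
#' @param fit A `ptcl_survfit` object or family name.
#' @param cycles Number of weekly cycles.
#' @param params Parameter vector when `fit` is a family name.
#' @return Numeric vector `p[1..cycles]`, where `p[w]` is the probability of
#'   dying during week `w` conditional on being alive at its start.
#' @export
death_prob_vector <- function(fit, cycles, params = NULL) {
  suppressWarnings(weekly_death_prob(fit, seq_len(cycles) - 1, params = params))
}

#' Calibrate a survival family to a target median
#'
#' Solves S(median) = 0.5 for the family's free scale/rate parameter with
#' the shape parameter(s) held fixed. Closed forms are used where available;
#' the generalized gamma uses the exact log-location shift
#' `mu = log(m) - log(q0)` with `q0` the median at `mu = 0`.
#'
#' @param family Family name (see [surv_families()]).
#' @param target_median Target median survival in weeks (> 0).
#' @param fixed Named list/vector of fixed shape parameters: `shape` for
#'   weibull/gompertz/loglogistic, `sdlog` for lognormal, `sigma` and `Q`
#'   for gengamma; none for exponential.
#' @return Full named parameter vector in canonical order.
#' @examples
#' calibrate_to_median("exponential", 10)                 # rate = log(2)/10
#' calibrate_to_median("gompertz", 17.70, fixed = c(shape = 0.05))
#' @export
calibrate_to_median <- function(family, target_median, fixed = NULL) {
  stopifnot(target_median > 0)
  m <- target_median
  fixed <- as.list(fixed)
  need <- function(nm) {
    if (is.null(fixed[[nm]])) stop("calibration of ", family,
                                   " requires fixed parameter '", nm, "'")
    fixed[[nm]]
  }
  params <- switch(family,
    exponential = c(rate = log(2) / m),
    weibull = {
      sh <- need("shape")
      c(shape = sh, scale = m / log(2)^(1 / sh))
    },
    gompertz = {
      a <- need("shape")
      b <- if (abs(a) < 1e-12) log(2) / m else a * log(2) / (expm1(a * m))
      if (b <= 0) stop("no feasible Gompertz rate for this shape and median")
      c(shape = a, rate = b)
    },
    loglogistic = c(shape = need("shape"), scale = m),
    lognormal = c(meanlog = log(m), sdlog = need("sdlog")),
    gengamma = {
      sigma <- need("sigma"); Q <- need("Q")
      q0 <- flexsurv::qgengamma(0.5, mu = 0, sigma = sigma, Q = Q)
      c(mu = log(m) - log(q0), sigma = sigma, Q = Q)
    },
    stop("unknown survival family: ", family)
  )
  achieved <- survival_at(family, m, params = params)
  if (abs(achieved - 0.5) > 1e-8)
    stop("calibration failed: S(median) = ", achieved)
  params
}
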
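#' Specify a known parametric survival truth
#'
#' Bundles the ground truth from which synthetic survival evidence is
#' generated: a parametric family, its parameter vector, the number of
#' subjects, the administrative follow-up limit, a random-censoring rate and
#' a seed. The defaults of the evidence simulator ([simulate_evidence()])
#' emulate an 80-patient-per-arm matched comparison with roughly 52 months
#' of follow-up.
#'
#' @param family Survival family name (see [surv_families()]).
#' @param params Parameter vector in the family's canonical order.
#' @param n_subjects Number of subjects (>= 2).
#' @param max_followup Administrative censoring time in weeks (may be `Inf`).
#' @param censor_rate Probability that a subject receives a random
#'   (uniform on (0, `max_followup`)) censoring time; in \[0, 1).
#' @param seed Integer seed for reproducible draws.
#' @return An object of class `ptcl_truth`.
#' @export
true_survival_spec <- function(family, params, n_subjects,
                               max_followup = Inf, censor_rate = 0,
                               seed = 1L) {
  params <- .check_params(family, params)
  stopifnot(n_subjects >= 2, max_followup > 0,
            censor_rate >= 0, censor_rate < 1)
  if (censor_rate > 0 && !is.finite(max_followup))
    stop("random censoring requires a finite max_followup")
  structure(list(family = family, params = params,
                 n_subjects = as.integer(n_subjects),
                 max_followup = max_followup, censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "ptcl_truth")
}

#' Draw individual patient data from a known truth
#'
#' Simulates `(time, event)` records: event times from the specified family,
#' censoring as the minimum of the event time, an optional uniform random
#' censoring draw (applied to each subject with probability `censor_rate`),
#' and the administrative follow-up limit. Identical specs (including seed)
#' give identical samples.
#'
#' @param spec A `ptcl_truth` from [true_survival_spec()].
#' @param arm_label Label stored in the `arm` column.
#' @return A `ptcl_ipd` data frame with columns `time` (weeks, > 0),
#'   `event` (logical) and `arm`.
#' @export
generate_ipd <- function(spec, arm_label = "arm") {
  stopifnot(inherits(spec, "ptcl_truth"))
  rfun <- .dist_fun("r", spec$family)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_subjects
  t_event <- do.call(rfun, c(list(n = n), as.list(spec$params)))
  t_event <- pmax(t_event, .Machine$double.eps)
  cens <- rep(Inf, n)
  if (spec$censor_rate > 0) {
    hit <- stats::runif(n) < spec$censor_rate
    cens[hit] <- stats::runif(sum(hit), 0, spec$max_followup)
  }
  limit <- pmin(cens, spec$max_followup)
  time <- pmin(t_event, limit)
  event <- t_event <= limit
  ipd <- data.frame(time = time, event = event, arm = arm_label,
                    stringsAsFactors = FALSE)
  class(ipd) <- c("ptcl_ipd", "data.frame")
  ipd
}

#' Emulate digitization of a published Kaplan-Meier curve
#'
#' Computes the exact Kaplan-Meier step function of an IPD sample, samples
#' it at every event (drop) time plus a regular grid, and optionally
#' perturbs the sampled survival values with Gaussian jitter to mimic
#' extraction error from a published figure. Jittered values are clamped to
#' \[0, 1\] and forced non-increasing (running-minimum clip). The first
#' coordinate is always (0, 1). Optionally emits a numbers-at-risk table at
#' regular interval times.
#'
#' @param ipd A `ptcl_ipd` data frame (or any data frame with `time` and
#'   `event` columns).
#' @param grid_step Grid spacing in weeks for additional sampled points
#'   (default 1).
#' @param jitter_sd Standard deviation of the extraction noise in survival
#'   probability units (default 0.005; 0 reproduces the exact estimate).
#' @param seed Optional seed for the jitter draws.
#' @param risk_table_interval If non-`NULL`, spacing in weeks of a
#'   numbers-at-risk table attached to the curve.
#' @return A `ptcl_curve` object: list with `coords` (data frame
#'   `time_weeks`, `survival`), optional `risk_table` (`time_weeks`,
#'   `n_at_risk`), and `total_n`.
#' @export
digitize_emulate <- function(ipd, grid_step = 1, jitter_sd = 0.005,
                             seed = NULL, risk_table_interval = NULL) {
  stopifnot(nrow(ipd) > 0, grid_step > 0, jitter_sd >= 0)
  km <- km_estimator(ipd)
  t_max <- max(ipd$time)
  times <- sort(unique(c(
    km$table$time[km$table$n_event > 0],
    seq(0, t_max, by = grid_step)
  )))
  times <- times[times > 0]
  s <- km_survival_at(km, times)
  if (jitter_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    s <- s + stats::rnorm(length(s), 0, jitter_sd)
    s <- pmin(pmax(s, 0), 1)
    s <- cummin(s)
  }
  coords <- data.frame(time_weeks = c(0, times), survival = c(1, s))
  risk_table <- NULL
  if (!is.null(risk_table_interval)) {
    rt_times <- seq(0, t_max, by = risk_table_interval)
    n_at_risk <- vapply(rt_times, function(tt) sum(ipd$time >= tt), numeric(1))
    risk_table <- data.frame(time_weeks = rt_times, n_at_risk = n_at_risk)
  }
  structure(list(coords = coords, risk_table = risk_table,
                 total_n = nrow(ipd)),
            class = "ptcl_curve")
}

#' Read / write digitized curves and IPD as CSV
#'
#' Curves are stored as CSV with columns `time_weeks`, `survival`; the
#' optional numbers-at-risk table as a companion CSV with `time_weeks`,
#' `n_at_risk`. IPD is stored with columns `time_weeks`, `event` (0/1) and
#' `arm`.
#'
#' @param curve A `ptcl_curve` object.
#' @param path CSV path for the coordinates.
#' @param risk_path Optional CSV path for the risk table.
#' @param total_n Total number at risk at time zero (needed on read when no
#'   risk table is given).
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_curve <- function(curve, path, risk_path = NULL) {
  utils::write.csv(curve$coords, path, row.names = FALSE)
  if (!is.null(risk_path) && !is.null(curve$risk_table))
    utils::write.csv(curve$risk_table, risk_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path, risk_path = NULL, total_n = NULL) {
  coords <- utils::read.csv(path)
  stopifnot(all(c("time_weeks", "survival") %in% names(coords)))
  risk_table <- NULL
  if (!is.null(risk_path)) {
    risk_table <- utils::read.csv(risk_path)
    stopifnot(all(c("time_weeks", "n_at_risk") %in% names(risk_table)))
  }
  if (is.null(total_n)) {
    if (is.null(risk_table)) stop("total_n required when no risk table is given")
    total_n <- risk_table$n_at_risk[which.min(risk_table$time_weeks)]
  }
  curve <- structure(list(coords = coords, risk_table = risk_table,
                          total_n = as.integer(total_n)),
                     class = "ptcl_curve")
  .validate_curve(curve)
  curve
}

#' @rdname write_curve
#' @param ipd A `ptcl_ipd` data frame.
#' @export
write_ipd <- function(ipd, path) {
  out <- data.frame(time_weeks = ipd$time, event = as.integer(ipd$event),
                    arm = if ("arm" %in% names(ipd)) ipd$arm else "arm")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_weeks", "event") %in% names(d)))
  ipd <- data.frame(time = d$time_weeks, event = d$event > 0,
                    arm = if ("arm" %in% names(d)) d$arm else "arm",
                    stringsAsFactors = FALSE)
  class(ipd) <- c("ptcl_ipd", "data.frame")
  ipd
}
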
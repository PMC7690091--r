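.validate_curve <- function(curve) {
  co <- curve$coords
  if (nrow(co) < 1) stop("empty curve")
  if (co$time_weeks[1] != 0 || abs(co$survival[1] - 1) > 1e-9)
    stop("curve must start at (0, 1)")
  if (any(diff(co$time_weeks) <= 0)) stop("coordinate times must be strictly increasing")
  if (any(co$survival < -1e-12 | co$survival > 1 + 1e-12))
    stop("survival coordinates outside [0, 1]")
  if (any(diff(co$survival) > 1e-12))
    stop("non-monotone survival input: coordinates must be non-increasing")
  if (!is.null(curve$risk_table)) {
    rt <- curve$risk_table
    if (any(diff(rt$time_weeks) <= 0)) stop("risk-table times must be strictly increasing")
    if (any(diff(rt$n_at_risk) > 0)) stop("risk-table counts must be non-increasing")
  }
  if (is.null(curve$total_n) || curve$total_n < 1) stop("total_n must be >= 1")
  invisible(curve)
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Inverts a digitized Kaplan-Meier curve into `(time, event)` records whose
#' re-estimated Kaplan-Meier curve reproduces the input coordinates (the
#' Guyot approach). Two modes:
#'
#' * **With a numbers-at-risk table**: within each risk interval, integer
#'   numbers of events per drop and of censorings between drops are found by
#'   deterministic search, minimizing the squared deviation of the implied
#'   survival from each coordinate; at every risk-table time the remaining
#'   at-risk count is reconciled by censoring the surplus inside the
#'   preceding gap. On noiseless coordinates this recovers the generating
#'   risk sets exactly.
#' * **Without a risk table** (the default evidence situation, total n
#'   only): no censoring is assumed before the end of follow-up; events are
#'   allocated from the survival ratios scaled by `total_n`, and all
#'   remaining subjects are censored at the last coordinate time.
#'
#' Events and censorings always sum to `total_n` exactly.
#'
#' @param curve A `ptcl_curve` (see [digitize_emulate()] / [read_curve()]).
#' @param arm_label Label stored in the `arm` column.
#' @return A `ptcl_ipd` data frame with columns `time`, `event`, `arm`.
#' @export
reconstruct_ipd <- function(curve, arm_label = "arm") {
  .validate_curve(curve)
  co <- curve$coords
  co <- co[co$time_weeks > 0, , drop = FALSE]
  rt <- curve$risk_table
  has_rt <- !is.null(rt) && nrow(rt) > 0
  if (has_rt) rt <- rt[order(rt$time_weeks), , drop = FALSE]

  n_avail <- as.integer(curve$total_n)
  s_model <- 1
  prev_time <- 0
  ev_times <- numeric(0)
  cn_times <- numeric(0)
  rt_ptr <- 1L

  censor_in_gap <- function(k, from, to) {
    if (k <= 0) return(numeric(0))
    from + (to - from) * seq_len(k) / (k + 1)
  }

  # censor down to the observed at-risk count at each risk-table boundary
  apply_boundaries <- function(upto_time, interval_end) {
    while (has_rt && rt_ptr <= nrow(rt) && rt$time_weeks[rt_ptr] <= upto_time + 1e-12) {
      tt <- rt$time_weeks[rt_ptr]
      n_obs <- rt$n_at_risk[rt_ptr]
      if (n_avail < n_obs - 0L)
        stop("risk table inconsistent with coordinates at interval ", rt_ptr,
             " (time ", tt, "): needs ", n_obs, " at risk, only ", n_avail,
             " remain")
      surplus <- n_avail - as.integer(n_obs)
      if (surplus > 0) {
        cn_times <<- c(cn_times, censor_in_gap(surplus, prev_time, tt))
        n_avail <<- n_avail - surplus
      }
      rt_ptr <<- rt_ptr + 1L
    }
  }

  next_risk_n <- function() {
    if (has_rt && rt_ptr <= nrow(rt)) as.integer(rt$n_at_risk[rt_ptr]) else NULL
  }

  for (i in seq_len(nrow(co))) {
    t_i <- co$time_weeks[i]
    s_i <- co$survival[i]
    apply_boundaries(t_i, t_i)
    if (n_avail <= 0 || s_model <= 0) break
    r <- 1 - s_i / s_model
    if (r <= 0) { prev_time <- t_i; next }
    nn <- next_risk_n()
    c_max <- if (!has_rt) 0L else if (is.null(nn)) 0L else max(0L, n_avail - nn)
    best <- NULL
    for (cc in 0:c_max) {
      n_i <- n_avail - cc
      if (n_i <= 0) break
      d <- max(0L, min(n_i, as.integer(round(r * n_i))))
      err <- (s_model * (1 - d / n_i) - s_i)^2
      if (is.null(best) || err < best$err - 1e-30) best <- list(c = cc, d = d, err = err)
      if (best$err < 1e-24) break
    }
    if (!is.null(best) && best$d > 0) {
      if (best$c > 0) {
        cn_times <- c(cn_times, censor_in_gap(best$c, prev_time, t_i))
        n_avail <- n_avail - best$c
      }
      ev_times <- c(ev_times, rep(t_i, best$d))
      s_model <- s_model * (1 - best$d / n_avail)
      n_avail <- n_avail - best$d
    }
    prev_time <- t_i
  }

  # trailing risk-table entries beyond the last coordinate
  if (has_rt && rt_ptr <= nrow(rt)) apply_boundaries(max(rt$time_weeks), NA)

  end_time <- max(c(co$time_weeks, if (has_rt) rt$time_weeks else numeric(0)))
  if (n_avail > 0) {
    cn_times <- c(cn_times, rep(end_time, n_avail))
    n_avail <- 0L
  }

  ipd <- data.frame(
    time = c(ev_times, cn_times),
    event = c(rep(TRUE, length(ev_times)), rep(FALSE, length(cn_times))),
    arm = arm_label, stringsAsFactors = FALSE
  )
  ipd <- ipd[order(ipd$time, -ipd$event), ]
  rownames(ipd) <- NULL
  stopifnot(nrow(ipd) == curve$total_n)
  class(ipd) <- c("ptcl_ipd", "data.frame")
  ipd
}
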
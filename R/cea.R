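#' Weekly discount factor
#'
#' Continuous-in-week compounding: `(1 + rate)^(-week / weeks_per_year)`.
#'
#' @param week Week index/indices (0 = start of simulation).
#' @param annual_rate Annual discount rate (>= 0; 0.05 in the base case).
#' @param weeks_per_year Weeks per year (default 52.1).
#' @return Discount multiplier(s) in (0, 1].
#' @export
discount_factor <- function(week, annual_rate, weeks_per_year = 52.1) {
  stopifnot(all(week >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-week / weeks_per_year)
}

# per-week unit-cost schedules for one arm, aligned with cycles 1..n
.cost_schedules <- function(arm, params, schedule) {
  n <- attr(schedule, "cycles")
  phase <- schedule$phase
  wop <- schedule$week_of_phase
  cs <- params$costs
  dose <- if (arm == "cc") cs$cc_dose_multiplier else 1

  med <- numeric(n); conc <- numeric(n); mon <- numeric(n); ae <- numeric(n)
  init <- phase == "initial_tx"
  sub <- phase == "subsequent_tx"

  if (arm == "pralatrexate") {
    cyc <- params$tx_cycle_weeks$pralatrexate_initial
    med[init] <- cs$medication$pralatrexate_initial
    conc[init] <- ifelse(wop[init] <= cyc,
                         cs$concomitant$pralatrexate_initial_first,
                         cs$concomitant$pralatrexate_initial_last)
    mon[init] <- ifelse(wop[init] <= cyc,
                        cs$monitoring$pralatrexate_initial_first,
                        cs$monitoring$pralatrexate_initial_other)
    ae_init_prob <- params$ae$prob_pralatrexate_initial
  } else {
    cyc <- params$tx_cycle_weeks$cc_initial
    med[init] <- cs$medication$cc_initial * dose
    conc[init] <- cs$concomitant$cc_initial
    mon[init] <- ifelse(wop[init] <= cyc, cs$monitoring$cc_initial_first,
                        cs$monitoring$cc_initial_other)
    ae_init_prob <- params$ae$prob_cc_initial
  }
  cyc_s <- params$tx_cycle_weeks$subsequent
  med[sub] <- cs$medication$subsequent * dose
  conc[sub] <- cs$concomitant$subsequent
  mon[sub] <- ifelse(wop[sub] <= cyc_s, cs$monitoring$subsequent_first,
                     cs$monitoring$subsequent_other)
  ae[init] <- sum(ae_init_prob * params$ae$cost)
  ae[sub] <- sum(params$ae$prob_subsequent * params$ae$cost)
  list(medication = med, concomitant = conc, monitoring = mon, ae = ae,
       init = init, sub = sub)
}

#' Accrue discounted life-years and QALYs over a cohort trace
#'
#' Each weekly cycle contributes `alive mass x 1/52.1 x discount` life-years
#' (start-of-cycle occupancy, no half-cycle correction). QALYs weight each
#' compartment by its response-state utility (CR 0.885, PR 0.784, SD 0.746,
#' PD 0.567), the SCT-success state by the age-band general-population
#' utility, and subtract the expected adverse-event disutility
#' (`sum(weekly probability x disutility)`) from mass occupying a treatment
#' phase; the net utility is floored at 0.
#'
#' @param trace A `ptcl_trace` from [run_cohort()].
#' @param params A `ptcl_params` object.
#' @param discount Logical; apply discounting (default `TRUE`).
#' @return List with `ly` and `qaly` (discounted unless `discount = FALSE`).
#' @export
accrue_effects <- function(trace, params, discount = TRUE) {
  n <- nrow(trace) - 1
  arm <- attr(trace, "arm")
  wpy <- params$weeks_per_year
  disc <- if (discount) discount_factor(0:(n - 1), params$discount_annual, wpy)
          else rep(1, n)
  occ <- trace[seq_len(n), , drop = FALSE]  # start-of-cycle occupancy
  age <- attr(trace, "age")[seq_len(n)]

  resp <- c("CR", "PR", "SD", "PD")
  u <- params$utilities
  du_init <- if (arm == "pralatrexate")
    sum(params$ae$prob_pralatrexate_initial * params$ae$disutility)
  else sum(params$ae$prob_cc_initial * params$ae$disutility)
  du_sub <- sum(params$ae$prob_subsequent * params$ae$disutility)

  qaly_w <- numeric(n)
  for (ph in c("initial", "pause1", "subsequent", "pause2")) {
    du <- switch(ph, initial = du_init, subsequent = du_sub, 0)
    for (r in resp) {
      u_eff <- max(u[[r]] + du, 0)
      qaly_w <- qaly_w + occ[, paste0(ph, "_", r)] * u_eff
    }
  }
  qaly_w <- qaly_w + occ[, "sct_success"] * sct_utility_at_age(params, age)
  alive <- 1 - occ[, "dead"]
  list(ly = sum(alive / wpy * disc), qaly = sum(qaly_w / wpy * disc))
}

#' Accrue discounted costs by category over a cohort trace
#'
#' Applies the per-week unit-cost schedules (medication, concomitant drugs
#' with first/last-cycle rates, monitoring with first/other-cycle rates) to
#' start-of-cycle treatment-phase occupancy; expected adverse-event
#' treatment costs (`sum(weekly probability x cost per episode)`) to the
#' same mass; and the one-off SCT cost to all transplanted mass (successes
#' and failures) at the week-20 and week-42 events, discounted at the event
#' week. Pause states accrue no costs.
#'
#' @param trace A `ptcl_trace`.
#' @param params A `ptcl_params` object.
#' @param schedule The arm's `ptcl_schedule` from [build_schedule()].
#' @param discount Logical; apply discounting (default `TRUE`).
#' @return Named list of the seven recurring/one-off cost categories
#'   (`initial_tx_medication`, `concomitant_initial`,
#'   `subsequent_tx_medication`, `concomitant_subsequent`,
#'   `monitoring_initial`, `monitoring_subsequent`, `ae_treatment`, `sct`)
#'   plus `total`.
#' @export
accrue_costs <- function(trace, params, schedule, discount = TRUE) {
  n <- nrow(trace) - 1
  if (attr(schedule, "cycles") != n)
    stop("schedule covers ", attr(schedule, "cycles"), " cycles but trace has ", n)
  arm <- attr(trace, "arm")
  if (!identical(attr(schedule, "arm"), arm))
    stop("schedule arm does not match trace arm")
  disc <- if (discount) discount_factor(0:(n - 1), params$discount_annual,
                                        params$weeks_per_year)
          else rep(1, n)
  occ <- trace[seq_len(n), , drop = FALSE]
  resp <- c("CR", "PR", "SD", "PD")
  mass_init <- rowSums(occ[, paste0("initial_", resp), drop = FALSE])
  mass_sub <- rowSums(occ[, paste0("subsequent_", resp), drop = FALSE])
  sc <- .cost_schedules(arm, params, schedule)

  sct_events <- attr(trace, "sct_events")
  sct_cost <- if (is.null(sct_events)) 0 else {
    dsct <- if (discount) discount_factor(sct_events$week, params$discount_annual,
                                          params$weeks_per_year)
            else rep(1, nrow(sct_events))
    sum(sct_events$transplanted * params$sct$cost * dsct)
  }

  out <- list(
    initial_tx_medication   = sum(mass_init * sc$medication[seq_len(n)] * disc * sc$init),
    concomitant_initial     = sum(mass_init * sc$concomitant * disc * sc$init),
    subsequent_tx_medication = sum(mass_sub * sc$medication * disc * sc$sub),
    concomitant_subsequent  = sum(mass_sub * sc$concomitant * disc * sc$sub),
    monitoring_initial      = sum(mass_init * sc$monitoring * disc * sc$init),
    monitoring_subsequent   = sum(mass_sub * sc$monitoring * disc * sc$sub),
    ae_treatment            = sum((mass_init * sc$init + mass_sub * sc$sub) *
                                    sc$ae * disc),
    sct                     = sct_cost
  )
  out$total <- sum(unlist(out))
  out
}

#' Full cost-effectiveness accounting for one arm
#'
#' Runs the cohort model and accrues discounted costs, life-years and QALYs.
#'
#' @param arm `"pralatrexate"` or `"cc"`.
#' @param params A `ptcl_params` object.
#' @param fit A `ptcl_survfit` (or death-probability vector/function)
#'   driving the arm's weekly death probabilities.
#' @param life_table A life table from [make_life_table()].
#' @return A `ptcl_cea` object: list with `arm`, `costs` (category list with
#'   total), `ly`, `qaly`, and the settings used.
#' @export
run_cea <- function(arm, params, fit, life_table) {
  dp <- if (inherits(fit, "ptcl_survfit")) death_prob_vector(fit, params$cycles)
        else fit
  schedule <- build_schedule(arm, params)
  trace <- run_cohort(arm, params, dp, life_table)
  eff <- accrue_effects(trace, params)
  costs <- accrue_costs(trace, params, schedule)
  structure(list(arm = arm, costs = costs, ly = eff$ly, qaly = eff$qaly,
                 discount_annual = params$discount_annual,
                 cycles = params$cycles, trace = trace),
            class = "ptcl_cea")
}

#' Incremental cost-effectiveness comparison
#'
#' Differences (a - b) in total cost, life-years and QALYs, with ICERs per
#' life-year and per QALY. Zero effect differences yield an undefined-ICER
#' flag (never infinities); sign-discordant quadrants set a dominance flag
#' (`"dominant"` when a is cheaper and more effective, `"dominated"` when a
#' is costlier and less effective).
#'
#' @param a,b Either `ptcl_cea` objects or lists with elements `total`
#'   (cost), `ly`, `qaly`.
#' @return A `ptcl_icer` object: list with `delta_cost`, `delta_ly`,
#'   `delta_qaly`, `icer_per_ly`, `icer_per_qaly`, `icer_defined`,
#'   `dominance`.
#' @examples
#' incremental(list(total = 48677, ly = 3.499, qaly = 1.075),
#'             list(total = 20045, ly = 1.932, qaly = 0.344))
#' @export
incremental <- function(a, b) {
  get_tot <- function(x) if (inherits(x, "ptcl_cea")) x$costs$total else x$total
  if (inherits(a, "ptcl_cea") && inherits(b, "ptcl_cea")) {
    if (a$cycles != b$cycles || a$discount_annual != b$discount_annual)
      stop("arms were run under different horizon/discount settings")
  }
  dc <- get_tot(a) - get_tot(b)
  dly <- a$ly - b$ly
  dq <- a$qaly - b$qaly
  ratio <- function(de) if (abs(de) > 0) dc / de else NA_real_
  dominance <- if (dc < 0 && (dly > 0 || dq > 0)) "dominant"
               else if (dc > 0 && (dly < 0 || dq < 0)) "dominated"
               else "none"
  structure(list(delta_cost = dc, delta_ly = dly, delta_qaly = dq,
                 icer_per_ly = ratio(dly), icer_per_qaly = ratio(dq),
                 icer_defined = c(per_ly = abs(dly) > 0, per_qaly = abs(dq) > 0),
                 dominance = dominance),
            class = "ptcl_icer")
}

#' Results table in the published two-arm layout
#'
#' @param a,b `ptcl_cea` objects (intervention, comparator).
#' @param inc Optional precomputed [incremental()] result.
#' @return Data frame: one row per cost category, life-years, QALYs and
#'   ICERs; columns for each arm and the incremental value.
#' @export
cea_table <- function(a, b, inc = incremental(a, b)) {
  cats <- c("total", "initial_tx_medication", "concomitant_initial",
            "subsequent_tx_medication", "concomitant_subsequent",
            "monitoring_initial", "monitoring_subsequent", "ae_treatment", "sct")
  rows <- data.frame(
    quantity = c(paste0("cost_", cats), "ly", "qaly", "icer_per_ly", "icer_per_qaly"),
    stringsAsFactors = FALSE
  )
  va <- c(unlist(a$costs[cats]), a$ly, a$qaly, NA, NA)
  vb <- c(unlist(b$costs[cats]), b$ly, b$qaly, NA, NA)
  vi <- c(unlist(a$costs[cats]) - unlist(b$costs[cats]), inc$delta_ly,
          inc$delta_qaly, inc$icer_per_ly, inc$icer_per_qaly)
  rows[[a$arm]] <- unname(va)
  rows[[b$arm]] <- unname(vb)
  rows$incremental <- unname(vi)
  rows
}
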
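#' Compartment names of the cohort model
#'
#' Sixteen living treatment compartments — the cross of four phases
#' (initial treatment, first pause, subsequent treatment, second pause) with
#' four response states (CR/PR/SD/PD) — plus the SCT-success and death
#' states. The two pause phases are tracked separately because only the
#' second pause is eligible for the week-42 transplantation event.
#'
#' @return Character vector of 18 compartment names.
#' @export
cohort_compartments <- function() {
  resp <- c("CR", "PR", "SD", "PD")
  c(paste0("initial_", resp), paste0("pause1_", resp),
    paste0("subsequent_", resp), paste0("pause2_", resp),
    "sct_success", "dead")
}

#' Build the weekly treatment-phase schedule for an arm
#'
#' Deterministic timeline shared by both arms: initial treatment weeks 1-14
#' (pralatrexate: two 7-week cycles; conventional chemotherapy: 4.67 3-week
#' cycles), pause weeks 15-22 with SCT at week 20, subsequent treatment
#' (conventional chemotherapy in both arms, 4.33 3-week cycles) weeks 23-35,
#' then a second pause from week 36 to the horizon with SCT at week 42. The
#' arms differ only in drug identity and costs.
#'
#' @param arm `"pralatrexate"` or `"cc"`.
#' @param params A `ptcl_params` object.
#' @return A `ptcl_schedule`: data frame with columns `week` (1..cycles),
#'   `phase` (initial_tx / pause1 / subsequent_tx / pause2) and
#'   `week_of_phase`; attributes `arm`, `sct_weeks`, `cycles`.
#' @export
build_schedule <- function(arm = c("pralatrexate", "cc"), params) {
  arm <- match.arg(arm)
  validate_parameters(params)
  tl <- params$timeline
  n <- params$cycles
  phase <- rep("pause2", n)
  phase[seq_len(tl$initial_tx_weeks)] <- "initial_tx"
  phase[(tl$initial_tx_weeks + 1):(tl$subsequent_start_week - 1)] <- "pause1"
  phase[tl$subsequent_start_week:(tl$pause2_start_week - 1)] <- "subsequent_tx"
  week <- seq_len(n)
  week_of_phase <- stats::ave(week, phase, FUN = seq_along)
  sched <- data.frame(week = week, phase = phase, week_of_phase = week_of_phase)
  attr(sched, "arm") <- arm
  attr(sched, "sct_weeks") <- c(initial = tl$sct_week_initial,
                                subsequent = tl$sct_week_subsequent)
  attr(sched, "cycles") <- n
  class(sched) <- c("ptcl_schedule", "data.frame")
  sched
}

#' Run the weekly Markov cohort simulation for one arm
#'
#' The cohort starts with mass 1 in the initial-treatment state, split
#' across CR/PR/SD/PD by the arm's initial response rates. Each weekly
#' cycle applies, in order: (i) the arm-level death probability (from the
#' extrapolated overall-survival curve) to every living non-SCT-success
#' compartment and the general-population (life-table) death probability at
#' the cohort's current age to the SCT-success compartment; then (ii) any
#' boundary event scheduled at the start of the next week:
#'
#' * week 15: initial treatment -> first pause (response mix carried over);
#' * week 20 boundary: of the surviving CR and PR mass, the fraction
#'   `sct_prob_initial * sct_success` moves to SCT success (transplant
#'   failures stay put with their response label);
#' * week 23: PR/SD/PD mass moves to subsequent treatment, CR remains in
#'   pause permanently;
#' * week 36: subsequent-treatment survivors enter the second pause,
#'   re-split by the post-subsequent response rates;
#' * week 42 boundary: second SCT event with `sct_prob_subsequent`.
#'
#' Transplant candidates must survive the SCT week before moving. Occupancy
#' rows always sum to 1 (checked to 1e-12 each cycle).
#'
#' @param arm `"pralatrexate"` or `"cc"`.
#' @param params A `ptcl_params` object.
#' @param death_prob Either a function `f(week_index)` (0-based, giving the
#'   probability of death during week `week_index + 1`) or a numeric vector
#'   of length `params$cycles`.
#' @param life_table A life table from [make_life_table()]; pass a table of
#'   zeros to disable background mortality.
#' @return A `ptcl_trace`: matrix of dimension `(cycles + 1) x 18` (rows are
#'   weeks 0..cycles), with attributes `age` (cohort age per row), `arm`,
#'   and `sct_events` (data frame `week`, `transplanted`, `succeeded`).
#' @export
run_cohort <- function(arm = c("pralatrexate", "cc"), params, death_prob,
                       life_table) {
  arm <- match.arg(arm)
  validate_parameters(params)
  n <- params$cycles
  tl <- params$timeline
  dp <- if (is.function(death_prob)) death_prob(0:(n - 1)) else death_prob
  if (length(dp) != n) stop("death_prob must cover all ", n, " cycles")
  if (any(dp < 0 | dp > 1)) stop("death probability outside [0,1]")

  comps <- cohort_compartments()
  resp <- c("CR", "PR", "SD", "PD")
  idx <- stats::setNames(seq_along(comps), comps)
  living <- setdiff(comps, c("sct_success", "dead"))

  split0 <- if (arm == "pralatrexate") params$response$pralatrexate_initial
            else params$response$cc_initial
  split_sub <- params$response$subsequent

  trace <- matrix(0, nrow = n + 1, ncol = length(comps),
                  dimnames = list(NULL, comps))
  x <- stats::setNames(numeric(length(comps)), comps)
  x[paste0("initial_", resp)] <- split0[resp]
  trace[1, ] <- x

  age <- params$start_age + (0:n) / params$weeks_per_year
  sct_frac_init <- params$sct$prob_initial
  sct_frac_sub <- params$sct$prob_subsequent
  sct_succ <- params$sct$success
  sct_log <- list()

  for (t in seq_len(n)) {
    # deaths during week t
    p_arm <- dp[t]
    p_gen <- life_table_weekly_prob(life_table, age[t])
    died <- sum(x[living]) * p_arm + x["sct_success"] * p_gen
    x[living] <- x[living] * (1 - p_arm)
    x["sct_success"] <- x["sct_success"] * (1 - p_gen)
    x["dead"] <- x["dead"] + died

    # boundary events effective at the start of week t + 1
    if (t == tl$initial_tx_weeks) {
      x[paste0("pause1_", resp)] <- x[paste0("pause1_", resp)] + x[paste0("initial_", resp)]
      x[paste0("initial_", resp)] <- 0
    }
    if (t == tl$sct_week_initial) {
      elig <- x[c("pause1_CR", "pause1_PR")]
      transplanted <- sum(elig) * sct_frac_init
      moved <- elig * sct_frac_init * sct_succ
      x[c("pause1_CR", "pause1_PR")] <- elig - moved
      x["sct_success"] <- x["sct_success"] + sum(moved)
      sct_log <- c(sct_log, list(data.frame(week = t, transplanted = transplanted,
                                            succeeded = sum(moved))))
    }
    if (t == tl$subsequent_start_week - 1) {
      mv <- c("PR", "SD", "PD")
      x[paste0("subsequent_", mv)] <- x[paste0("subsequent_", mv)] + x[paste0("pause1_", mv)]
      x[paste0("pause1_", mv)] <- 0
    }
    if (t == tl$pause2_start_week - 1) {
      mass <- sum(x[paste0("subsequent_", resp)])
      x[paste0("subsequent_", resp)] <- 0
      x[paste0("pause2_", resp)] <- x[paste0("pause2_", resp)] + mass * split_sub[resp]
    }
    if (t == tl$sct_week_subsequent) {
      elig <- x[c("pause2_CR", "pause2_PR")]
      transplanted <- sum(elig) * sct_frac_sub
      moved <- elig * sct_frac_sub * sct_succ
      x[c("pause2_CR", "pause2_PR")] <- elig - moved
      x["sct_success"] <- x["sct_success"] + sum(moved)
      sct_log <- c(sct_log, list(data.frame(week = t, transplanted = transplanted,
                                            succeeded = sum(moved))))
    }

    if (abs(sum(x) - 1) > 1e-9) stop("mass leak at cycle ", t, ": ", sum(x))
    trace[t + 1, ] <- x
  }

  attr(trace, "age") <- age
  attr(trace, "arm") <- arm
  attr(trace, "sct_events") <- do.call(rbind, sct_log)
  class(trace) <- c("ptcl_trace", class(trace))
  trace
}

#' Alive fraction per week of a cohort trace
#'
#' @param trace A `ptcl_trace` from [run_cohort()].
#' @return Numeric vector of length `nrow(trace)`: `1 - dead`, week 0 first;
#'   non-increasing.
#' @export
trace_survival <- function(trace) {
  as.numeric(1 - trace[, "dead"])
}

#' Export a cohort trace as CSV
#'
#' @param trace A `ptcl_trace`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(week = seq_len(nrow(trace)) - 1, as.data.frame(unclass(trace)),
                   age = attr(trace, "age"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
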
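#' Build the one-way sensitivity-analysis scenarios
#'
#' The deterministic scenario set examined around the base case:
#'
#' * survival-distribution swaps: each arm's extrapolation family replaced
#'   by every alternative converged candidate (extremes over the grid are
#'   reported);
#' * each health-state utility (CR/PR/SD/PD) at the bounds of its 95%
#'   confidence interval — the source intervals are not published, so the
#'   bounds are configuration with a default of +/-10% of the point
#'   estimate (capped at 1);
#' * SCT success probability varied by +/-10%;
#' * comparator drug dose reduced 20% with proportionally reduced
#'   comparator medication costs (high bound = base);
#' * simulation horizon at 10 and 30 years.
#'
#' @param params A `ptcl_params` object.
#' @param utility_ci Optional named list (`CR`, `PR`, `SD`, `PD`) of
#'   `c(low, high)` utility bounds overriding the +/-10% default.
#' @param sct_rel Relative variation of the SCT success probability
#'   (default 0.10).
#' @param dose_cut Comparator dose reduction (default 0.20).
#' @param horizons Horizon bounds in years (default `c(10, 30)`).
#' @return List of `ptcl_scenario` objects (name, type, low, high).
#' @export
build_scenarios <- function(params, utility_ci = NULL, sct_rel = 0.10,
                            dose_cut = 0.20, horizons = c(10, 30)) {
  sc <- list(list(name = "survival_distribution", type = "distribution",
                  low = NA, high = NA))
  for (r in c("CR", "PR", "SD", "PD")) {
    u <- params$utilities[[r]]
    bounds <- if (!is.null(utility_ci[[r]])) utility_ci[[r]]
              else c(u * 0.9, min(u * 1.1, 1))
    sc <- c(sc, list(list(name = paste0("utility_", r), type = "utility",
                          field = r, low = bounds[1], high = bounds[2])))
  }
  s <- params$sct$success
  sc <- c(sc, list(
    list(name = "sct_success", type = "sct_success",
         low = s * (1 - sct_rel), high = min(s * (1 + sct_rel), 1)),
    list(name = "cc_dose", type = "dose", low = 1 - dose_cut, high = 1),
    list(name = "horizon", type = "horizon", low = horizons[1], high = horizons[2])
  ))
  lapply(sc, function(x) structure(x, class = "ptcl_scenario"))
}

.apply_scenario <- function(params, scenario, value) {
  switch(scenario$type,
    utility = { params$utilities[[scenario$field]] <- value; params },
    sct_success = { params$sct$success <- value; params },
    dose = { params$costs$cc_dose_multiplier <- value; params },
    horizon = set_horizon(params, value),
    params
  )
}

#' Run the one-way sensitivity analysis
#'
#' Reruns the full cohort model and accounting at each bound of every
#' scenario, all other parameters held at base values; parameter objects are
#' modified on copies, so the base case is untouched and reproducible after
#' the batch. The distribution scenario evaluates the ICER over the grid of
#' converged families for both arms and reports the extremes.
#'
#' @param scenarios Scenario list from [build_scenarios()].
#' @param params Base-case `ptcl_params`.
#' @param fits_pral,fits_cc Named lists of `ptcl_survfit` per family (from
#'   [fit_all_families()]) for the two arms.
#' @param life_table A life table.
#' @param base_families Families driving the base case, default
#'   `c(pralatrexate = "gengamma", cc = "gompertz")`.
#' @return A `ptcl_tornado` data frame: one row per scenario with the
#'   perturbed values (`value_low`, `value_high`), the resulting ICERs per
#'   QALY (`icer_low`, `icer_high`), the base ICER, and the tornado `range`.
#'   Scenario failures are recorded in the `error` column, not raised.
#' @export
run_one_way <- function(scenarios, params, fits_pral, fits_cc, life_table,
                        base_families = c(pralatrexate = "gengamma",
                                          cc = "gompertz")) {
  fit_p <- fits_pral[[base_families[["pralatrexate"]]]]
  fit_c <- fits_cc[[base_families[["cc"]]]]
  icer_for <- function(p, fp = fit_p, fc = fit_c) {
    a <- run_cea("pralatrexate", p, fp, life_table)
    b <- run_cea("cc", p, fc, life_table)
    incremental(a, b)$icer_per_qaly
  }
  base_icer <- icer_for(params)

  rows <- lapply(scenarios, function(sc) {
    out <- data.frame(scenario = sc$name, value_low = NA_character_,
                      value_high = NA_character_, icer_low = NA_real_,
                      icer_high = NA_real_, icer_base = base_icer,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      if (sc$type == "distribution") {
        ok_p <- Filter(function(f) isTRUE(f$converged), fits_pral)
        ok_c <- Filter(function(f) isTRUE(f$converged), fits_cc)
        grid <- expand.grid(p = names(ok_p), c = names(ok_c),
                            stringsAsFactors = FALSE)
        icers <- mapply(function(fp, fc) icer_for(params, ok_p[[fp]], ok_c[[fc]]),
                        grid$p, grid$c)
        out$icer_low <- min(icers); out$icer_high <- max(icers)
        lo <- which.min(icers); hi <- which.max(icers)
        out$value_low <- paste0(grid$p[lo], "/", grid$c[lo])
        out$value_high <- paste0(grid$p[hi], "/", grid$c[hi])
      } else {
        out$value_low <- format(sc$low); out$value_high <- format(sc$high)
        out$icer_low <- icer_for(.apply_scenario(params, sc, sc$low))
        out$icer_high <- icer_for(.apply_scenario(params, sc, sc$high))
      }
      out
    }, error = function(e) { out$error <- conditionMessage(e); out })
  })
  res <- do.call(rbind, rows)
  res$range <- abs(res$icer_high - res$icer_low)
  attr(res, "base_icer") <- base_icer
  class(res) <- c("ptcl_tornado", "data.frame")
  res
}

#' Order sensitivity results for a tornado diagram
#'
#' Sorts scenarios by decreasing ICER range; ties keep their input order
#' (stable sort).
#'
#' @param table A `ptcl_tornado` data frame from [run_one_way()].
#' @return The reordered table.
#' @export
tornado_order <- function(table) {
  stopifnot(nrow(table) > 0)
  out <- table[order(-table$range), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write tornado results as CSV and plot-ready JSON
#'
#' @param table A (preferably ordered) `ptcl_tornado` data frame.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return The table, invisibly.
#' @export
write_tornado <- function(table, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(table), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(base_icer = attr(table, "base_icer"),
           bars = as.data.frame(table)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(table)
}
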
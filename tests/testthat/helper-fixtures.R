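# shared fixtures, all built in code

# the 5-subject worked example: 1 event at t=1, 2 events at t=2, 2 censored at t=2
tiny_ipd <- function() {
  structure(
    data.frame(time = c(1, 2, 2, 2, 2),
               event = c(TRUE, TRUE, TRUE, FALSE, FALSE),
               arm = "toy", stringsAsFactors = FALSE),
    class = c("ptcl_ipd", "data.frame"))
}

# a ptcl_survfit built directly from known parameters (no fitting)
make_fit <- function(family, params) {
  structure(list(family = family, params = params, loglik = NA_real_,
                 aic = NA_real_, bic = NA_real_, n = NA_integer_,
                 n_events = NA_integer_, converged = TRUE, override = FALSE),
            class = "ptcl_survfit")
}

# life table with zero mortality at every age
zero_life_table <- function() make_life_table(makeham_a = 0, gompertz_b = 0)

# calibrated truth fits used across tests (base-case-like survival inputs)
base_fits <- function() {
  list(
    pral = make_fit("gengamma",
                    calibrate_to_median("gengamma", 15.24 * weeks_per_month(),
                                        fixed = c(sigma = 1, Q = 1))),
    cc = make_fit("gompertz",
                  calibrate_to_median("gompertz", 4.07 * weeks_per_month(),
                                      fixed = c(shape = 0.05)))
  )
}
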
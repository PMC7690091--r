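test_that("discount factors follow the fractional-week convention", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(0:500, 0), rep(1, 501))
  expect_equal(discount_factor(52, 0.05), 1.05^(-52 / 52.1))
  expect_equal(discount_factor(52, 0.05), 0.95247, tolerance = 1e-5)
  expect_true(all(diff(discount_factor(0:100, 0.05)) < 0))
})

test_that("a hand-built two-week PD trace accrues the expected LY and QALY", {
  p <- default_parameters()
  p$discount_annual <- 0
  comps <- cohort_compartments()
  tr <- matrix(0, nrow = 3, ncol = length(comps),
               dimnames = list(NULL, comps))
  tr[1, "pause2_PD"] <- 1
  tr[2, "pause2_PD"] <- 0.5; tr[2, "dead"] <- 0.5
  tr[3, "dead"] <- 1
  attr(tr, "age") <- 48 + (0:2) / 52.1
  attr(tr, "arm") <- "cc"
  class(tr) <- c("ptcl_trace", class(tr))
  eff <- accrue_effects(tr, p)
  expect_equal(eff$ly, 1.5 / 52.1)
  expect_equal(eff$qaly, 0.567 * 1.5 / 52.1)
})

test_that("a CR year accrues about one LY weighted by the CR utility", {
  p <- default_parameters()
  p$discount_annual <- 0
  p$response$pralatrexate_initial <- c(CR = 1, PR = 0, SD = 0, PD = 0)
  p$sct$prob_initial <- 0; p$sct$prob_subsequent <- 0
  tr <- run_cohort("pralatrexate", p, rep(0, p$cycles), zero_life_table())
  eff <- accrue_effects(tr, p)
  expect_equal(eff$ly, 782 / 52.1)  # zero-hazard limit
  # CR utility everywhere, minus the AE decrement during the 14 treatment weeks
  du <- sum(p$ae$prob_pralatrexate_initial * p$ae$disutility)
  expect_equal(eff$qaly, (14 * (0.885 + du) + (782 - 14) * 0.885) / 52.1,
               tolerance = 1e-10)
})

test_that("QALYs equal LYs when utility is perfect", {
  p <- default_parameters()
  p$utilities[] <- 1
  p$sct_utility$utility[] <- 1
  p$ae$disutility[] <- 0
  fits <- base_fits()
  tr <- run_cohort("cc", p, death_prob_vector(fits$cc, p$cycles),
                   make_life_table())
  eff <- accrue_effects(tr, p)
  expect_equal(eff$qaly, eff$ly, tolerance = 1e-12)
})

test_that("accrued costs match an independent week-by-week tally", {
  p <- default_parameters()
  lt <- make_life_table()
  fits <- base_fits()
  for (arm in c("pralatrexate", "cc")) {
    fit <- if (arm == "pralatrexate") fits$pral else fits$cc
    sched <- build_schedule(arm, p)
    tr <- run_cohort(arm, p, death_prob_vector(fit, p$cycles), lt)
    got <- accrue_costs(tr, p, sched)

    # naive loop oracle
    resp <- c("CR", "PR", "SD", "PD")
    cs <- p$costs
    tot <- c(med_i = 0, con_i = 0, med_s = 0, con_s = 0, mon_i = 0,
             mon_s = 0, ae = 0)
    for (w in seq_len(p$cycles)) {
      occ <- tr[w, ]
      d <- 1.05^(-(w - 1) / 52.1)
      mi <- sum(occ[paste0("initial_", resp)])
      ms <- sum(occ[paste0("subsequent_", resp)])
      if (sched$phase[w] == "initial_tx") {
        if (arm == "pralatrexate") {
          tot["med_i"] <- tot["med_i"] + mi * 2465 * d
          tot["con_i"] <- tot["con_i"] + mi * (if (w <= 7) 4 else 3) * d
          tot["mon_i"] <- tot["mon_i"] + mi * (if (w <= 7) 106 else 17) * d
          tot["ae"] <- tot["ae"] + mi * sum(p$ae$prob_pralatrexate_initial * p$ae$cost) * d
        } else {
          tot["med_i"] <- tot["med_i"] + mi * 240 * d
          tot["con_i"] <- tot["con_i"] + mi * 207 * d
          tot["mon_i"] <- tot["mon_i"] + mi * (if (w <= 3) 129 else 40) * d
          tot["ae"] <- tot["ae"] + mi * sum(p$ae$prob_cc_initial * p$ae$cost) * d
        }
      }
      if (sched$phase[w] == "subsequent_tx") {
        wop <- w - 22
        tot["med_s"] <- tot["med_s"] + ms * 238 * d
        tot["con_s"] <- tot["con_s"] + ms * 198 * d
        tot["mon_s"] <- tot["mon_s"] + ms * (if (wop <= 3) 123 else 38) * d
        tot["ae"] <- tot["ae"] + ms * sum(p$ae$prob_subsequent * p$ae$cost) * d
      }
    }
    expect_equal(got$initial_tx_medication, unname(tot["med_i"]), tolerance = 1e-9)
    expect_equal(got$concomitant_initial, unname(tot["con_i"]), tolerance = 1e-9)
    expect_equal(got$subsequent_tx_medication, unname(tot["med_s"]), tolerance = 1e-9)
    expect_equal(got$concomitant_subsequent, unname(tot["con_s"]), tolerance = 1e-9)
    expect_equal(got$monitoring_initial, unname(tot["mon_i"]), tolerance = 1e-9)
    expect_equal(got$monitoring_subsequent, unname(tot["mon_s"]), tolerance = 1e-9)
    expect_equal(got$ae_treatment, unname(tot["ae"]), tolerance = 1e-9)

    # SCT cost: transplanted mass (successes and failures) at the event weeks
    ev <- attr(tr, "sct_events")
    expect_equal(got$sct,
                 sum(ev$transplanted * 27343 * 1.05^(-ev$week / 52.1)),
                 tolerance = 1e-9)
    # category additivity
    expect_equal(got$total,
                 sum(unlist(got[setdiff(names(got), "total")])),
                 tolerance = 1e-6)
  }
})

test_that("one week of CC initial AE expectation matches the hand sum", {
  p <- default_parameters()
  ae_week <- sum(p$ae$prob_cc_initial * p$ae$cost)
  hand <- 0.0365 * 1288 + 0.1122 * 2859 + 0.0257 * 2877 + 0.1250 * 2760 +
    0.0053 * 707 + 0.0063 * 643
  expect_equal(ae_week, hand)
  expect_equal(hand, 794.5, tolerance = 1e-3)
  # order of magnitude over a full mortality-free initial phase
  expect_equal(14 * hand, 11123, tolerance = 0.01)
})

test_that("discounting can only shrink costs, and scaling is exact", {
  p <- default_parameters()
  lt <- make_life_table()
  fits <- base_fits()
  sched <- build_schedule("pralatrexate", p)
  tr <- run_cohort("pralatrexate", p, death_prob_vector(fits$pral, p$cycles), lt)
  disc <- accrue_costs(tr, p, sched, discount = TRUE)
  undisc <- accrue_costs(tr, p, sched, discount = FALSE)
  for (nm in names(disc)) expect_lte(disc[[nm]], undisc[[nm]])
  expect_lt(accrue_effects(tr, p)$ly, accrue_effects(tr, p, discount = FALSE)$ly)

  # scale every unit cost by 3: all categories scale by exactly 3
  p3 <- p
  p3$costs$medication <- lapply(p$costs$medication, `*`, 3)
  p3$costs$concomitant <- lapply(p$costs$concomitant, `*`, 3)
  p3$costs$monitoring <- lapply(p$costs$monitoring, `*`, 3)
  p3$ae$cost <- p$ae$cost * 3
  p3$sct$cost <- p$sct$cost * 3
  tripled <- accrue_costs(tr, p3, sched)
  for (nm in names(disc)) expect_equal(tripled[[nm]], 3 * disc[[nm]])
  expect_equal(accrue_effects(tr, p3)$qaly, accrue_effects(tr, p)$qaly)
})

test_that("incremental results reproduce ratio arithmetic and flags", {
  inc <- incremental(list(total = 48677, ly = 3.499, qaly = 1.075),
                     list(total = 20045, ly = 1.932, qaly = 0.344))
  expect_equal(inc$delta_cost, 28632)
  expect_equal(inc$delta_ly, 1.567)
  expect_equal(inc$delta_qaly, 0.731)
  expect_equal(inc$icer_per_qaly, 28632 / 0.731)
  expect_equal(inc$dominance, "none")

  same <- list(total = 100, ly = 1, qaly = 1)
  inc0 <- incremental(same, same)
  expect_true(is.na(inc0$icer_per_qaly))
  expect_false(inc0$icer_defined[["per_qaly"]])

  expect_equal(incremental(list(total = 2000, ly = 1, qaly = 1.5),
                           list(total = 1000, ly = 0.5, qaly = 1))$icer_per_qaly,
               2000)
  expect_equal(incremental(list(total = 90, ly = 2, qaly = 2),
                           list(total = 100, ly = 1, qaly = 1))$dominance,
               "dominant")
  expect_equal(incremental(list(total = 110, ly = 0.5, qaly = 0.5),
                           list(total = 100, ly = 1, qaly = 1))$dominance,
               "dominated")
})

test_that("the two-arm results table is internally consistent", {
  p <- default_parameters()
  lt <- make_life_table()
  fits <- base_fits()
  bc <- run_base_case(p, fits$pral, fits$cc, lt)
  tab <- bc$table
  expect_equal(tab$incremental[tab$quantity == "cost_total"],
               bc$incremental$delta_cost)
  expect_equal(tab$incremental[tab$quantity == "icer_per_qaly"],
               bc$incremental$icer_per_qaly)
  expect_equal(tab$pralatrexate[tab$quantity == "qaly"], bc$pralatrexate$qaly)
  # mismatched settings are refused
  p10 <- set_horizon(p, 10)
  b10 <- run_cea("cc", p10, fits$cc, lt)
  expect_error(incremental(bc$pralatrexate, b10), "different horizon")
})
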
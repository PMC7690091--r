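#!/usr/bin/env Rscript
# Step 1 — synthesize the survival evidence.
#
# The comparative overall-survival evidence (two 80-patient arms, medians
# 15.24 and 4.07 months) is not publicly available, so it is emulated from
# parametric truths calibrated to those published medians, followed by an
# emulated digitization of the Kaplan-Meier curves (1-week grid, extraction
# noise sd 0.005). Outputs: per-arm digitized-curve and IPD CSVs plus the
# truth parameters.

suppressPackageStartupMessages(library(ptclcua))

seed <- 20260921L
dir.create("results/evidence", recursive = TRUE, showWarnings = FALSE)

ev <- simulate_evidence(seed = seed)

truth <- list(seed = seed)
for (arm in c("pralatrexate", "cc")) {
  write_curve(ev[[arm]]$curve, sprintf("results/evidence/curve_%s.csv", arm))
  write_ipd(ev[[arm]]$ipd, sprintf("results/evidence/ipd_true_%s.csv", arm))
  truth[[arm]] <- list(family = ev[[arm]]$truth$family,
                       params = as.list(ev[[arm]]$truth$params))
  km <- km_estimator(ev[[arm]]$ipd)
  med <- median_survival(km)
  message(sprintf("%-12s truth %s, sampled KM median %.2f weeks (%.2f months)",
                  arm, ev[[arm]]$truth$family, med$weeks,
                  med$weeks / weeks_per_month()))
}
jsonlite::write_json(c(truth, list(settings = ev$settings)),
                     "results/evidence/truth.json",
                     auto_unbox = TRUE, digits = NA)
message("wrote results/evidence/ (curves, true IPD, truth.json)")
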
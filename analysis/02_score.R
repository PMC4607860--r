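#!/usr/bin/env Rscript
# Score the simulated response streams: d-prime time courses per
# participant and for the count-pooled average, empirical asymptotes
# (mean of the last four d' values), and correct-rejection profiles for
# the control (interpolated-anomaly) vs experimental (final-anomaly)
# unacceptable conditions.

library(satdyn)

spec <- design_spec()
for (cohort in c("univ", "comm")) {
  trials <- read_trials(sprintf("results/%s_trials.csv", cohort), spec)
  curves <- dprime_curves(trials, spec)
  write_curves(curves, sprintf("results/%s_curves.csv", cohort))
  crp <- cr_profile(trials, spec)
  utils::write.csv(crp, sprintf("results/%s_cr_profile.csv", cohort),
                   row.names = FALSE)

  avg <- curves[curves$participant == "average", ]
  emp <- empirical_asymptote(avg)
  cat(sprintf("\n%s cohort, averaged data:\n", cohort))
  print(emp, row.names = FALSE)
  cat("correct rejections, interpolated anomaly (lags 2-15):\n ")
  cat(sprintf("%.1f", 100 * crp$cr[crp$group == "interpolated_anomaly"]),
      sep = " ")
  cat("\ncorrect rejections, final anomaly (lags 2-15):\n ")
  cat(sprintf("%.1f", 100 * crp$cr[crp$group == "final_anomaly"]), sep = " ")
  cat("\n")
}
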
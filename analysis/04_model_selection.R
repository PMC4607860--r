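#!/usr/bin/env Rscript
# Nested-model comparison: per-participant adjusted-R^2 consistency for
# every nested pair in the fitted ladder, and the preferred-model verdict
# (averaged-data gain + participant majority, parsimony, intercept-over-rate
# tie-break).

library(satdyn)

for (cohort in c("univ", "comm")) {
  lad <- readRDS(sprintf("results/%s_ladder.rds", cohort))
  rep <- consistency_report(lad)
  sel <- select_preferred(lad, reports = rep)
  utils::write.csv(rep$summary, sprintf("results/%s_consistency.csv", cohort),
                   row.names = FALSE)
  cat(sprintf("\n== %s cohort ==\n", cohort))
  print(rep)
  print(sel)
}
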
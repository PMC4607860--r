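test_that("nested comparisons subtract adjusted R-squared and guard units", {
  curves <- noiseless_curves(reference_params()$comm_3l1b2d)
  set.seed(2)
  curves$dprime <- curves$dprime + rnorm(nrow(curves), 0, 0.05)
  f_small <- fit_model(curves, "1l-1b-1d", quick_cfg())
  f_large <- fit_model(curves, "3l-1b-2d", quick_cfg())
  expect_equal(compare_nested(f_small, f_large),
               f_large$adj_r2 - f_small$adj_r2)
  # equal adjusted R^2 values give a zero delta
  f_tied <- f_large; f_tied$adj_r2 <- f_small$adj_r2
  expect_equal(compare_nested(f_small, f_tied), 0)
  f_other <- f_large; f_other$unit <- "someone-else"
  expect_error(compare_nested(f_small, f_other), "different data units")
  expect_error(compare_nested(f_large, f_small), "fewer parameters")
})

test_that("consistency reports summarize per-participant improvements", {
  co <- small_cohort(n = 5, seed = 61, trials_per_cell = 24)
  cu <- dprime_curves(co$trials, design_spec())
  lad <- fit_ladder(cu, c("2l-1b-1d", "3l-1b-1d"), quick_cfg())
  rep1 <- consistency_report(lad)
  expect_equal(nrow(rep1$summary), 1)
  r <- rep1$reports[[1]]
  expect_equal(r$n_improved, sum(r$deltas > 0))
  expect_equal(r$n + length(r$excluded), 5)
  expect_equal(r$mean, mean(r$deltas))
  expect_equal(r$min, min(r$deltas))
  expect_equal(r$max, max(r$deltas))
  expect_true(is.finite(r$avg_delta))
})

test_that("separated asymptotes select the three-asymptote two-intercept model", {
  # well-separated asymptotes and intercepts, modest cohort
  base <- generative_params(trials_per_cell = 24,
                            delta = c(NoInterp = 0.8, OR = 1.6, `OR+SR` = 1.6))
  co <- simulate_cohort(design_spec(),
                        cohort_params(8, base = base, seed = 62), seed = 62)
  cu <- dprime_curves(co$trials, design_spec())
  lad <- fit_ladder(cu, c("1l-1b-1d", "2l-1b-1d", "3l-1b-1d", "3l-1b-2d",
                          "3l-1b-3d"), quick_cfg())
  sel <- select_preferred(lad)
  expect_equal(sel$preferred, "3l-1b-2d")
  expect_true(sel$justified[["3l-1b-1d"]])
})

test_that("null-generated data retain the null model", {
  base <- generative_params(
    lambda = c(NoInterp = 2, OR = 2, `OR+SR` = 2),
    beta = 1, delta = 0.8, ability_slope_lambda = 0, trials_per_cell = 12)
  co <- simulate_cohort(design_spec(),
                        cohort_params(5, base = base, sd_lambda = 0,
                                      sd_log_beta = 0, sd_delta = 0,
                                      seed = 63), seed = 63)
  cu <- dprime_curves(co$trials, design_spec())
  lad <- fit_ladder(cu, c("1l-1b-1d", "2l-1b-1d"), quick_cfg())
  sel <- select_preferred(lad)
  expect_equal(sel$preferred, "1l-1b-1d")
})

test_that("verdicts are invariant to participant order and handle one candidate", {
  co <- small_cohort(n = 4, seed = 64, trials_per_cell = 24)
  cu <- dprime_curves(co$trials, design_spec())
  lad <- fit_ladder(cu, c("2l-1b-1d", "3l-1b-1d"), quick_cfg())
  sel <- select_preferred(lad)
  lad_rev <- lad
  lad_rev$participants <- rev(lad$participants)
  for (nm in names(lad_rev$models)) {
    lad_rev$models[[nm]]$participants <-
      rev(lad_rev$models[[nm]]$participants)
  }
  expect_equal(select_preferred(lad_rev)$preferred, sel$preferred)

  solo <- fit_ladder(cu, "3l-1b-2d", quick_cfg())
  expect_equal(select_preferred(solo)$preferred, "3l-1b-2d")
})
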
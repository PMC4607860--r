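test_that("noiseless curves from a known theta are recovered exactly", {
  truth <- list(lambda = c(NoInterp = 3.2, OR = 2.1, `OR+SR` = 1.1),
                beta = c(NoInterp = 1.4, OR = 1.4, `OR+SR` = 1.4),
                delta = c(NoInterp = 0.6, OR = 1.1, `OR+SR` = 1.1))
  curves <- noiseless_curves(truth)
  fit <- fit_model(curves, "3l-1b-2d", fit_config(seed = 5, restarts = 3))
  expect_equal(unname(fit$theta),
               c(3.2, 2.1, 1.1, 1.4, 0.6, 1.1), tolerance = 1e-3)
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-8)
  expect_false(fit$flags$asymptote_overestimated)
})

test_that("identically zero curves drive the asymptotes to the lower bound", {
  curves <- noiseless_curves(reference_params()$comm_3l1b2d)
  curves$dprime <- 0
  fit <- fit_model(curves, "3l-1b-2d", quick_cfg())
  expect_equal(fit$sse, 0, tolerance = 1e-12)
  pred <- predict_sat(fit$theta, fit$spec, curves$construction, curves$lag_time)
  expect_true(all(abs(pred) < 1e-8))
  expect_true(is.na(fit$adj_r2))  # zero-variance observations
})

test_that("more restarts can only improve the best objective (nested starts)", {
  co <- small_cohort(n = 1, seed = 51)
  cu <- dprime_curves(co$trials, design_spec(), include_average = FALSE)
  base <- fit_config(seed = 9, restarts = 1, algorithms = "port",
                     polish = FALSE)
  more <- fit_config(seed = 9, restarts = 8, algorithms = "port",
                     polish = FALSE)
  f1 <- fit_model(cu, "3l-1b-2d", base)
  f8 <- fit_model(cu, "3l-1b-2d", more)
  expect_lte(f8$sse, f1$sse + 1e-12)
  # first restart of the larger run is the single restart of the smaller
  expect_equal(f8$runs$objective[1], f1$runs$objective[1])
})

test_that("fits are deterministic given data, spec, config and seed", {
  co <- small_cohort(n = 1, seed = 52)
  cu <- dprime_curves(co$trials, design_spec(), include_average = FALSE)
  f1 <- fit_model(cu, "3l-1b-2d", quick_cfg(seed = 3))
  f2 <- fit_model(cu, "3l-1b-2d", quick_cfg(seed = 3))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$runs, f2$runs)
})

test_that("validity flags track empirical asymptotes and box bounds", {
  truth <- reference_params()$comm_3l1b2d
  curves <- noiseless_curves(truth)
  fit <- fit_model(curves, "3l-1b-2d", quick_cfg())
  expect_false(fit$flags$asymptote_overestimated)
  expect_false(fit$flags$at_bound)

  # forged fit: asymptote at the upper bound with a low empirical asymptote
  forged <- fit
  forged$theta[c("lambda1", "lambda2", "lambda3")] <- 6.0
  flags <- check_asymptotes(forged, curves)
  expect_true(flags$asymptote_overestimated)
  expect_true(flags$at_bound)

  # an asymptote floor of 0.4 makes low-asymptote conditions sit at the bound
  low <- truth
  low$lambda[["OR+SR"]] <- 0.25
  floor_cfg <- fit_config(lambda_bounds = c(0.4, 6), seed = 2, restarts = 3,
                          algorithms = c("port", "lbfgsb"))
  f_low <- fit_model(noiseless_curves(low), "3l-1b-2d", floor_cfg)
  expect_equal(unname(f_low$theta["lambda3"]), 0.4, tolerance = 1e-6)
  expect_true(f_low$flags$at_bound)
})

test_that("a ladder with growing asymptote counts improves fit on separated data", {
  truth <- list(lambda = c(NoInterp = 3.5, OR = 2.0, `OR+SR` = 0.9),
                beta = c(NoInterp = 1, OR = 1, `OR+SR` = 1),
                delta = c(NoInterp = 0.8, OR = 0.8, `OR+SR` = 0.8))
  curves <- noiseless_curves(truth)
  set.seed(4)
  curves$dprime <- curves$dprime + rnorm(nrow(curves), 0, 0.08)
  lad <- fit_ladder(curves, c("1l-1b-1d", "2l-1b-1d", "3l-1b-1d"), quick_cfg())
  r2 <- vapply(lad$models, function(m) m$average$adj_r2, numeric(1))
  expect_true(all(diff(r2) > 0))

  # data generated under the null: extra asymptotes are not rewarded
  null_truth <- list(lambda = c(NoInterp = 2, OR = 2, `OR+SR` = 2),
                     beta = truth$beta, delta = truth$delta)
  null_curves <- noiseless_curves(null_truth)
  lad0 <- fit_ladder(null_curves, c("1l-1b-1d", "2l-1b-1d"), quick_cfg())
  d0 <- compare_nested(lad0$models[["1l-1b-1d"]]$average,
                       lad0$models[["2l-1b-1d"]]$average)
  expect_lte(d0, 1e-8)

  expect_length(fit_ladder(curves, list(), quick_cfg())$models, 0)
})

test_that("warm-started ladders keep SSE monotone along nesting chains", {
  co <- small_cohort(n = 2, seed = 53)
  cu <- dprime_curves(co$trials, design_spec())
  chain <- c("1l-1b-1d", "2l-1b-1d", "3l-1b-1d", "3l-1b-2d", "3l-2b-2d")
  lad <- fit_ladder(cu, chain, quick_cfg())
  for (u in c("average", lad$participants)) {
    sses <- vapply(lad$models, function(m) {
      f <- if (u == "average") m$average else m$participants[[u]]
      if (inherits(f, "sat_fit")) f$sse else NA_real_
    }, numeric(1))
    expect_true(all(diff(sses[!is.na(sses)]) <= 1e-10))
  }
})
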
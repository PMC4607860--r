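spec <- design_spec()

test_that("zero asymptotes yield undecided (BOTH) responses at every lag", {
  gp <- generative_params(lambda = c(NoInterp = 0, OR = 0, `OR+SR` = 0),
                          ability_slope_lambda = 0)
  for (s in 1:5) {
    codes <- simulate_trial_lags(
      gp, list(construction = "OR", acceptable = TRUE, control_anomaly = FALSE),
      spec, seed = s)
    expect_true(all(codes == "BOTH"))
  }
})

test_that("decided-lag yes rates follow the equal-variance SDT rule", {
  # near-instantaneous rise: d(t) ~ lambda = 3 at every positive lag,
  # so P(YES | acceptable) = Phi(1.5) = 0.9331928 (frozen from the normal
  # CDF oracle)
  gp <- generative_params(lambda = c(NoInterp = 3, OR = 3, `OR+SR` = 3),
                          beta = 50, delta = 0, ability_slope_lambda = 0)
  trial <- list(construction = "NoInterp", acceptable = TRUE,
                control_anomaly = FALSE)
  yes <- vapply(1:400, function(s) {
    codes <- simulate_trial_lags(gp, trial, spec, seed = s)
    mean(codes[2:15] == "YES")
  }, numeric(1))
  p_hat <- mean(yes)
  se <- sqrt(0.9331928 * (1 - 0.9331928) / (400 * 14))
  expect_lt(abs(p_hat - 0.9331928), 4 * se + 1e-12)
})

test_that("an extreme criterion forces NO on every decided lag", {
  gp <- generative_params(criterion = 50, ability_slope_lambda = 0)
  codes <- simulate_trial_lags(
    gp, list(construction = "NoInterp", acceptable = TRUE,
             control_anomaly = FALSE), spec, seed = 3)
  decided <- codes != "BOTH"
  expect_true(any(decided))
  expect_true(all(codes[decided] == "NO"))
})

test_that("unknown constructions and invalid parameters are rejected", {
  gp <- generative_params()
  expect_error(simulate_trial_lags(
    gp, list(construction = "XX", acceptable = TRUE, control_anomaly = FALSE),
    spec, seed = 1), "unknown construction")
  expect_error(generative_params(lambda = c(A = -1)), "lambda")
  expect_error(generative_params(switch_prob = 0.7), "switch_prob")
})

test_that("rendered streams round-trip through parse_stream", {
  set.seed(42)
  for (i in 1:25) {
    codes <- sample(c("YES", "NO", "BOTH", "NONE"), spec$n_tones,
                    replace = TRUE)
    expect_identical(parse_stream(render_stream(codes, spec), spec), codes)
  }
  # structured sequences
  expect_identical(
    parse_stream(render_stream(c(rep("BOTH", 3), rep("YES", 12)), spec), spec),
    c(rep("BOTH", 3), rep("YES", 12)))
  st <- render_stream(rep("BOTH", 15), spec)
  expect_equal(sum(st$action == "down"), 2)  # both keys at first tone
  expect_equal(st$time_s[st$action == "up"], rep(4.8, 2))  # window end
  empty_spec <- design_spec(n_types = 1, items_per_type = 1, n_lists = 1,
                            n_tones = 0)
  expect_equal(nrow(render_stream(character(0), empty_spec)), 0)
  expect_error(render_stream(rep("YES", 3), spec), "15")
})

test_that("higher ability raises generated asymptotic accuracy, slope 0 does not", {
  slope_cor <- function(slope, seed) {
    co <- small_cohort(n = 16, seed = seed, ability_slope = slope,
                       sd_lambda = 0, sd_log_beta = 0, sd_delta = 0)
    cu <- dprime_curves(co$trials, design_spec(), include_average = FALSE)
    emp <- empirical_asymptote(cu)
    by_p <- tapply(emp$empirical_asymptote, emp$participant, mean)
    cor(co$abilities$ability[match(names(by_p), co$abilities$participant)],
        as.numeric(by_p))
  }
  expect_gt(slope_cor(0.5, seed = 7), 0.4)
  expect_lt(abs(slope_cor(0, seed = 7)), 0.45)
})

test_that("cohort substreams are stable under cohort enlargement", {
  base <- generative_params(trials_per_cell = 12L)
  co_small <- simulate_cohort(spec, cohort_params(4, base = base, seed = 5),
                              seed = 5)
  co_big <- simulate_cohort(spec, cohort_params(8, base = base, seed = 5),
                            seed = 5)
  p1_small <- co_small$trials[co_small$trials$participant == "P03", ]
  p1_big <- co_big$trials[co_big$trials$participant == "P03", ]
  rownames(p1_small) <- rownames(p1_big) <- NULL
  expect_identical(p1_small, p1_big)
})
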
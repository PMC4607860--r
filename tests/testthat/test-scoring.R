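spec <- design_spec()

test_that("parse_stream samples key state at tone onsets with half-open windows", {
  empty <- data.frame(participant = character(0), trial = integer(0),
                      time_s = numeric(0), key = character(0),
                      action = character(0))
  expect_identical(parse_stream(empty, spec), rep("NONE", 15))

  # both keys held before tone 1, switch to YES-only at tone 5 (t = 1.2 s)
  st <- data.frame(
    participant = "P01", trial = 1L,
    time_s = c(-0.5, -0.5, 1.2, 4.8),
    key = c("YES", "NO", "NO", "YES"),
    action = c("down", "down", "up", "up"))
  expect_identical(parse_stream(st, spec), c(rep("BOTH", 4), rep("YES", 11)))

  # a release exactly at a tone time means the key is not held at that tone
  st2 <- data.frame(participant = "P01", trial = 1L,
                    time_s = c(-0.5, 0.15), key = c("YES", "YES"),
                    action = c("down", "up"))
  expect_identical(parse_stream(st2, spec)[1:3], c("YES", "NONE", "NONE"))

  # malformed pairing: down while already down
  bad <- data.frame(participant = "P01", trial = 9L,
                    time_s = c(0, 0.5), key = "YES",
                    action = c("down", "down"))
  expect_error(parse_stream(bad, spec), "malformed event pairing")
})

test_that("d-prime follows z(hit) - z(fa) with the undecided and edge conventions", {
  # hit = fa = 0.5 -> d' = 0
  tr <- constant_trials(rep(c("YES", "NO"), 10), rep(c("YES", "NO"), 10))
  cu <- dprime_curves(tr, spec, include_average = FALSE)
  expect_true(all(cu$dprime == 0))

  # hit = 21/25 = 0.84, fa = 4/25 = 0.16 -> d' = 1.9889158
  # (two inverse-normal evaluations, frozen from the quantile oracle)
  tr <- constant_trials(rep(c("YES", "NO"), c(21, 4)),
                        rep(c("YES", "NO"), c(4, 21)))
  cu <- dprime_curves(tr, spec, include_average = FALSE)
  expect_equal(unique(round(cu$dprime, 7)), 1.9889158)

  # all-BOTH trials: hit = fa = 0.5 -> d' = 0
  tr <- constant_trials(rep("BOTH", 8), rep("BOTH", 8))
  cu <- dprime_curves(tr, spec, include_average = FALSE)
  expect_true(all(cu$dprime == 0))
})

test_that("d-prime is antisymmetric under swapping acceptability labels", {
  co <- small_cohort(n = 2, seed = 31)
  tr <- co$trials[!co$trials$control_anomaly, ]
  cu <- dprime_curves(tr, spec, include_average = FALSE)
  swapped <- tr
  swapped$acceptable <- !swapped$acceptable
  cu2 <- dprime_curves(swapped, spec, include_average = FALSE)
  key <- paste(cu$participant, cu$construction, cu$lag)
  key2 <- paste(cu2$participant, cu2$construction, cu2$lag)
  expect_equal(cu2$dprime[match(key, key2)], -cu$dprime)
})

test_that("edge correction bounds d-prime by the cell size", {
  # unanimous responses: hit clipped to 1 - 1/(2N), fa to 1/(2N)
  tr <- constant_trials(rep("YES", 12), rep("NO", 12))
  cu <- dprime_curves(tr, spec, include_average = FALSE)
  bound <- 2 * qnorm(1 - 1 / (2 * 12))
  expect_true(all(is.finite(cu$dprime)))
  expect_equal(unique(cu$dprime), bound)
  expect_true(all(abs(cu$dprime) <= bound + 1e-12))
})

test_that("a construction missing a response cell raises a data error naming it", {
  tr <- constant_trials(rep("YES", 4), rep("NO", 4))
  tr <- tr[tr$acceptable, ]  # drop all unacceptable trials
  expect_error(dprime_curves(tr, spec), "unacceptable")
  # all-NONE lag: scorable-denominator failure at a specific lag
  tr2 <- constant_trials(rep("YES", 4), rep("NONE", 4))
  expect_error(dprime_curves(tr2, spec), "lag")
})

test_that("the averaged curve pools trial counts across participants", {
  co <- small_cohort(n = 3, seed = 17)
  tr <- co$trials
  cu <- dprime_curves(tr, spec)
  avg <- cu[cu$participant == "average" & cu$construction == "OR", ]
  # pooled counts are the sum of per-participant counts
  per <- cu[cu$participant != "average" & cu$construction == "OR" & cu$lag == 15, ]
  expect_equal(avg$n_acc[avg$lag == 15], sum(per$n_acc))
  # count pooling differs from averaging per-participant d-primes
  cu_mean <- dprime_curves(tr, spec, average = "mean")
  avg_mean <- cu_mean[cu_mean$participant == "average" &
                        cu_mean$construction == "OR", ]
  expect_false(isTRUE(all.equal(avg$dprime, avg_mean$dprime)))
})

test_that("the averaged curve converges to the generating SAT curve", {
  base <- generative_params(trials_per_cell = 48L, ability_slope_lambda = 0)
  co <- simulate_cohort(spec, cohort_params(12, base = base, sd_lambda = 0,
                                            sd_log_beta = 0, sd_delta = 0,
                                            seed = 3), seed = 3)
  cu <- dprime_curves(co$trials, spec)
  avg <- cu[cu$participant == "average", ]
  tt <- lag_times(spec)
  ref <- reference_params()$comm_3l1b2d
  sup <- max(vapply(sat_conditions(), function(cn) {
    obs <- avg$dprime[avg$construction == cn][order(avg$lag[avg$construction == cn])]
    truth <- evaluate_sat(ref$lambda[[cn]], ref$beta[[cn]], ref$delta[[cn]], tt)
    max(abs(obs - truth))
  }, numeric(1)))
  expect_lt(sup, 0.3)   # 576 trials per cell per lag: binomial error only
  expect_lt(mean(abs(avg$dprime - evaluate_sat(
    ref$lambda[avg$construction], ref$beta[avg$construction],
    ref$delta[avg$construction], avg$lag_time))), 0.08)
})

test_that("empirical asymptote averages the last m d-prime values", {
  expect_equal(empirical_asymptote(rep(2, 10)), 2)
  expect_equal(empirical_asymptote(c(0, 0, 1, 2, 3, 4)), 2.5)
  expect_equal(empirical_asymptote(c(1, 5), m = 1), 5)
  expect_error(empirical_asymptote(c(1, 2), m = 4), "argument error")
})

test_that("correct-rejection profiles separate control and experimental anomalies", {
  tr_both <- constant_trials(rep("BOTH", 4), rep("BOTH", 4),
                             sentence_type_acc = "T3",
                             sentence_type_unacc = "T4")
  ctrl <- constant_trials(rep("BOTH", 4), rep("BOTH", 4),
                          sentence_type_acc = "T3",
                          sentence_type_unacc = "T5")
  ctrl$control_anomaly[!ctrl$acceptable] <- TRUE
  crp <- cr_profile(rbind(tr_both, ctrl), spec)
  expect_true(all(crp$cr == 0.5))
  expect_equal(sort(unique(crp$group)),
               c("final_anomaly", "interpolated_anomaly"))
  expect_equal(unique(crp$lag), 2:15)

  # simulated cohorts: profiles rise from ~0.5 and stay in [0, 1]
  co <- small_cohort(n = 8, seed = 23)
  crp2 <- cr_profile(co$trials, spec)
  for (g in unique(crp2$group)) {
    v <- crp2$cr[crp2$group == g][order(crp2$lag[crp2$group == g])]
    expect_true(all(v >= 0 & v <= 1))
    expect_lt(abs(v[1] - 0.5), 0.05)
    expect_gt(mean(v[11:14]), mean(v[1:4]) + 0.05)
  }
  expect_error(cr_profile(tr_both, spec), "control")
})
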
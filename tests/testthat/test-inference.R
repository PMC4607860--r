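# Parameter tables are built directly where possible; simulation-based
# checks reuse the cohort fixture.

toy_table <- function(values, abilities = NULL) {
  # values: matrix participants x levels
  p <- sprintf("P%02d", seq_len(nrow(values)))
  out <- expand.grid(participant = p, level = colnames(values),
                     stringsAsFactors = FALSE)
  out$quantity <- "lambda"
  out$value <- values[cbind(match(out$participant, p),
                            match(out$level, colnames(values)))]
  out$ability <- if (is.null(abilities)) NA_real_ else
    abilities[match(out$participant, p)]
  out
}

test_that("no condition effect yields a small F, identical shifts a large one", {
  set.seed(8)
  intercepts <- rnorm(8, 2, 0.5)
  vals <- outer(intercepts, c(A = 0, B = 0, C = 0), `+`) +
    matrix(rnorm(24, 0, 0.1), 8)
  colnames(vals) <- c("A", "B", "C")
  res <- mixed_anova(toy_table(vals), "lambda")
  expect_lt(res$anova$F[1], 3)
  expect_gt(res$anova$p[1], 0.05)

  # two near-identical participants with strongly distinct condition means
  vals2 <- rbind(c(A = 3, B = 2, C = 1), c(A = 3.01, B = 2.01, C = 0.99))
  res2 <- mixed_anova(toy_table(vals2), "lambda")
  expect_gt(res2$anova$F[1], 100)
  ct <- pairwise_contrasts(toy_table(vals2), "lambda")
  expect_true(all(ct$mean_diff[ct$pair == "A - C"] > 0))

  solo <- toy_table(vals2[1, , drop = FALSE])
  expect_error(mixed_anova(solo, "lambda"), "at least 2 participants")
})

test_that("contrasts follow the paired-t convention with degenerate sentinels", {
  vals <- matrix(rep(c(1.5, 2.5, 0.7), each = 4), 4,
                 dimnames = list(NULL, c("A", "B", "C")))
  ct <- pairwise_contrasts(toy_table(vals), "lambda")
  expect_true(all(ct$degenerate))
  ab <- ct[ct$pair == "A - B", ]
  expect_equal(ab$t, -Inf)  # constant shift, zero variance of differences
  expect_true(ab$significant)

  identical_tab <- toy_table(matrix(1, 4, 2, dimnames = list(NULL, c("A", "B"))))
  ct0 <- pairwise_contrasts(identical_tab, "lambda")
  expect_equal(ct0$t, 0)
  expect_false(ct0$significant)

  # t statistics are antisymmetric in the pair ordering
  set.seed(3)
  vals2 <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("A", "B")))
  t_ab <- pairwise_contrasts(toy_table(vals2), "lambda")$t
  t_ba <- pairwise_contrasts(toy_table(vals2[, c("B", "A")]), "lambda")$t
  expect_equal(t_ab, -t_ba)
})

test_that("ability slopes on the asymptote are detected on lambda only", {
  co <- small_cohort(n = 12, seed = 71, trials_per_cell = 48,
                     ability_slope = 0.5)
  cu <- dprime_curves(co$trials, design_spec(), include_average = FALSE)
  us <- unique(cu$participant)
  fits <- setNames(lapply(us, function(u) {
    fit_model(cu[cu$participant == u, ], "3l-1b-2d", quick_cfg(), unit = u)
  }), us)
  ptab <- parameter_table(fits, curves = cu, abilities = co$abilities)
  expect_true(all(table(ptab$participant, ptab$quantity) <= 3))

  res_l <- mixed_anova(ptab, "lambda", with_ability = TRUE)
  p_ability <- res_l$anova$p[res_l$anova$effect == "ability_z"]
  expect_lt(p_ability, 0.05)

  # construction ordering of asymptotes matches the generating order
  ct <- pairwise_contrasts(ptab, "lambda")
  expect_gt(ct$mean_diff[ct$pair == "NoInterp - OR"], 0)
  expect_gt(ct$mean_diff[ct$pair == "OR - OR+SR"], 0)
  expect_gt(ct$mean_diff[ct$pair == "NoInterp - OR+SR"], 0)

  # empirical asymptotes mirror the fitted ones
  res_e <- mixed_anova(ptab, "empirical_asymptote", with_ability = TRUE)
  expect_lt(res_e$anova$p[res_e$anova$effect == "ability_z"], 0.05)

  # the shared rate has one row per participant: OLS fallback, no effect
  res_b <- mixed_anova(ptab, "beta", with_ability = TRUE)
  expect_equal(nrow(res_b$anova), 1)
  expect_gt(res_b$anova$p[1], 0.01)
})
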
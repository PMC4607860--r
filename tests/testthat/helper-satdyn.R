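# Shared fixtures: all data are generated in code at test time.

# A fast fit configuration for simulation-heavy tests: two bounded
# algorithm families, two restarts, plus the polish step.
quick_cfg <- function(seed = 11L) {
  fit_config(seed = seed, restarts = 2L, algorithms = c("port", "lbfgsb"))
}

# Small cohort with known generating parameters.
small_cohort <- function(n = 6L, seed = 101L, trials_per_cell = 12L,
                         ability_slope = 0.3, sd_lambda = 0.2,
                         sd_log_beta = 0.2, sd_delta = 0.1, ...) {
  base <- generative_params(trials_per_cell = trials_per_cell,
                            ability_slope_lambda = ability_slope, ...)
  simulate_cohort(design_spec(),
                  cohort_params(n_participants = n, base = base,
                                sd_lambda = sd_lambda,
                                sd_log_beta = sd_log_beta,
                                sd_delta = sd_delta, seed = seed),
                  seed = seed)
}

# Lag-code trial table built directly (no simulation). `acc_trial_codes` and
# `unacc_trial_codes` give one code per trial; each trial holds that code at
# every lag.
constant_trials <- function(acc_trial_codes, unacc_trial_codes,
                            spec = design_spec(),
                            sentence_type_acc = "T1",
                            sentence_type_unacc = "T2") {
  lagcols <- paste0("lag_", seq_len(spec$n_tones))
  tm <- spec$type_map
  row <- function(i, st, acc, code) {
    r <- data.frame(participant = "P01", list = 1L, trial = i, item = st,
                    sentence_type = st,
                    construction = tm$construction[tm$sentence_type == st],
                    acceptable = acc, control_anomaly = FALSE,
                    stringsAsFactors = FALSE)
    r[lagcols] <- as.list(rep(code, spec$n_tones))
    r
  }
  n_acc <- length(acc_trial_codes)
  do.call(rbind, c(
    lapply(seq_len(n_acc), function(i)
      row(i, sentence_type_acc, TRUE, acc_trial_codes[i])),
    lapply(seq_along(unacc_trial_codes), function(i)
      row(n_acc + i, sentence_type_unacc, FALSE, unacc_trial_codes[i]))
  ))
}
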
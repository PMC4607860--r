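# Generative model for simulated MR-SAT response streams.
#
# Responding is equal-variance signal detection around a latent exponential
# d-prime curve: while the latent curve is at 0 the simulated participant
# holds both keys (undecided); once it rises above 0, a YES is emitted with
# probability Phi(d/2 - c) on acceptable trials and Phi(-d/2 - c) on
# unacceptable trials, which makes z(hit) - z(false alarm) recover the
# latent d exactly.

CODE_LEVELS <- c("YES", "NO", "BOTH", "NONE")

#' Generative parameters for one simulated participant
#'
#' @param lambda named asymptotes (d-prime) per construction condition.
#'   Defaults to the community-cohort averaged parameter set
#'   (see [reference_params()]).
#' @param beta named rates (1/s) per condition; scalar values are recycled.
#' @param delta named intercepts (s) per condition; scalars recycled.
#' @param criterion signal-detection criterion c in d-prime units
#'   (0 = unbiased).
#' @param ability scaled ability score (e.g. receptive vocabulary); `NA`
#'   means no ability adjustment.
#' @param ability_slope_lambda d-prime change in every asymptote per ability
#'   standard deviation; ability acts on the asymptote only.
#' @param switch_prob probability per lag of a momentary response flip
#'   (motor slip); must lie in 0..0.5. Default 0: per-lag responses are
#'   already independent draws given the latent curve.
#' @param control_lambda_scale fraction of the condition asymptote used for
#'   control-anomaly trials (anomaly inside the interpolated clause), whose
#'   correct rejections grow exponentially but below the experimental
#'   conditions.
#' @param decision_delay_meanlog,decision_delay_sdlog optional lognormal
#'   decision-delay jitter added to the intercept per trial; `NULL` (default)
#'   disables it.
#' @param trials_per_cell simulated trials per sentence type per participant
#'   (default 48: every participant hears all four lists, as in the full
#'   set of experimental sessions).
#' @return an object of class `sat_generative`.
#' @export
generative_params <- function(lambda = reference_params()$comm_3l1b2d$lambda,
                              beta = reference_params()$comm_3l1b2d$beta,
                              delta = reference_params()$comm_3l1b2d$delta,
                              criterion = 0,
                              ability = NA_real_,
                              ability_slope_lambda = 0.3,
                              switch_prob = 0,
                              control_lambda_scale = 0.8,
                              decision_delay_meanlog = NULL,
                              decision_delay_sdlog = NULL,
                              trials_per_cell = 48L) {
  conds <- names(lambda)
  if (is.null(conds)) stop_config("lambda must be a named vector (condition -> asymptote)")
  recycle <- function(x) {
    if (length(x) == 1L) x <- rep(x, length(conds))
    if (is.null(names(x))) names(x) <- conds
    x[conds]
  }
  beta <- recycle(beta); delta <- recycle(delta)
  if (any(lambda < 0) || any(beta <= 0) || any(delta < 0)) {
    stop_config("require lambda >= 0, beta > 0, delta >= 0 for every construction")
  }
  if (switch_prob < 0 || switch_prob > 0.5) {
    stop_config("switch_prob must lie in [0, 0.5]")
  }
  if (control_lambda_scale < 0) stop_config("control_lambda_scale must be non-negative")
  structure(list(
    lambda = lambda, beta = beta, delta = delta,
    criterion = criterion, ability = ability,
    ability_slope_lambda = ability_slope_lambda,
    switch_prob = switch_prob,
    control_lambda_scale = control_lambda_scale,
    decision_delay_meanlog = decision_delay_meanlog,
    decision_delay_sdlog = decision_delay_sdlog,
    trials_per_cell = as.integer(trials_per_cell)
  ), class = "sat_generative")
}

# Standardized ability of one participant (0 when no ability recorded).
ability_z <- function(gp) {
  pr <- ability_prior()
  if (is.finite(gp$ability)) (gp$ability - pr$mean) / pr$sd else 0
}

#' Draw per-participant generative parameters for a cohort
#'
#' Participants share the base parameter set, perturbed by modest
#' between-participant variation (additive normal jitter on asymptotes and
#' intercepts, lognormal on rates), and receive an ability score drawn from
#' the truncated-normal receptive-vocabulary prior ([ability_prior()]).
#' Ability shifts asymptotes only, through `ability_slope_lambda`.
#'
#' @param n_participants cohort size.
#' @param base a [generative_params()] object giving the cohort-level truth.
#' @param sd_lambda,sd_delta SD of additive per-participant jitter on the
#'   asymptotes (d-prime) and intercepts (s).
#' @param sd_log_beta SD of multiplicative (log-scale) jitter on the rates.
#' @param seed integer seed.
#' @return list with `participants` (list of `sat_generative`, one per
#'   participant) and `abilities` (data frame `participant`, `ability`).
#' @export
cohort_params <- function(n_participants = 22L,
                          base = generative_params(),
                          sd_lambda = 0.2, sd_log_beta = 0.2, sd_delta = 0.1,
                          seed = 1L) {
  stopifnot(inherits(base, "sat_generative"))
  pr <- ability_prior()
  participants <- vector("list", n_participants)
  abilities <- numeric(n_participants)
  for (p in seq_len(n_participants)) {
    with_seed(hash_mix(seed, "cohort", p), {
      a <- pr$mean + pr$sd * stats::rnorm(1)
      while (a < pr$lower || a > pr$upper) a <- pr$mean + pr$sd * stats::rnorm(1)
      lam <- pmax(base$lambda + stats::rnorm(length(base$lambda), 0, sd_lambda), 0)
      bet <- base$beta * exp(stats::rnorm(length(base$beta), 0, sd_log_beta))
      del <- pmax(base$delta + stats::rnorm(length(base$delta), 0, sd_delta), 0)
      abilities[p] <- a
      gp <- base
      gp$lambda <- lam; gp$beta <- bet; gp$delta <- del; gp$ability <- a
      participants[[p]] <- gp
    })
  }
  list(
    participants = participants,
    abilities = data.frame(participant = sprintf("P%02d", seq_len(n_participants)),
                           ability = abilities, stringsAsFactors = FALSE)
  )
}

#' Simulate the per-lag response codes of one trial
#'
#' At each response lag the latent discriminability is the exponential SAT
#' value for the trial's construction (asymptote shifted by
#' `ability_slope_lambda * standardized ability`, and scaled by
#' `control_lambda_scale` on control-anomaly trials). While the latent curve
#' is 0 the emitted code is `BOTH`; afterwards YES/NO responses are
#' independent equal-variance signal-detection draws, optionally flipped
#' with probability `switch_prob`.
#'
#' @param gp a [generative_params()] object.
#' @param trial list or one-row data frame with `construction`, `acceptable`,
#'   `control_anomaly`.
#' @param spec a [design_spec()].
#' @param seed integer seed for this trial's substream.
#' @return character vector of length `spec$n_tones` with values
#'   `"YES"`, `"NO"`, `"BOTH"`.
#' @export
simulate_trial_lags <- function(gp, trial, spec, seed = 1L) {
  stopifnot(inherits(gp, "sat_generative"), inherits(spec, "sat_design"))
  constr <- as.character(trial$construction)
  if (!constr %in% names(gp$lambda)) {
    stop_data("unknown construction '", constr, "' (no generative parameters)")
  }
  lam <- max(gp$lambda[[constr]] + gp$ability_slope_lambda * ability_z(gp), 0)
  if (isTRUE(trial$control_anomaly)) lam <- lam * gp$control_lambda_scale
  bet <- gp$beta[[constr]]
  del <- gp$delta[[constr]]
  tt <- lag_times(spec)
  with_seed(seed, {
    if (!is.null(gp$decision_delay_meanlog)) {
      del <- del + stats::rlnorm(1, gp$decision_delay_meanlog,
                                 gp$decision_delay_sdlog %||% 0.5)
    }
    d <- evaluate_sat(lam, bet, del, tt)
    acc <- isTRUE(trial$acceptable)
    evidence <- if (acc) d / 2 else -d / 2
    p_yes <- stats::pnorm(evidence - gp$criterion)
    yes <- stats::runif(length(tt)) < p_yes
    if (gp$switch_prob > 0) {
      yes <- xor(yes, stats::runif(length(tt)) < gp$switch_prob)
    }
    codes <- rep("BOTH", length(tt))
    decided <- d > 0
    codes[decided] <- ifelse(yes[decided], "YES", "NO")
    codes
  })
}

#' Simulate a full MR-SAT cohort
#'
#' Builds the stimulus lists, assigns each participant
#' `trials_per_cell / instances_per_type_per_list` lists (rotating through
#' the lists across participants), presents them in seeded random order, and
#' simulates every trial's per-lag response codes. Per-trial randomness comes
#' from substreams derived from (seed, participant, trial) so enlarging the
#' cohort leaves existing participants' data unchanged.
#'
#' @param spec a [design_spec()].
#' @param params result of [cohort_params()], or a single
#'   [generative_params()] object applied to every participant.
#' @param n_participants cohort size when `params` is a single parameter set.
#' @param seed integer root seed.
#' @return an object of class `sat_cohort`: list with `trials` (lag-code
#'   trial table), `abilities`, `spec`, and `params`.
#' @export
simulate_cohort <- function(spec = design_spec(), params = cohort_params(),
                            n_participants = NULL, seed = 1L) {
  stopifnot(inherits(spec, "sat_design"))
  if (inherits(params, "sat_generative")) {
    n_participants <- n_participants %||% 22L
    ids <- sprintf("P%02d", seq_len(n_participants))
    params <- list(
      participants = rep(list(params), n_participants),
      abilities = data.frame(participant = ids,
                             ability = vapply(rep(list(params), n_participants),
                                              function(g) g$ability, numeric(1)),
                             stringsAsFactors = FALSE)
    )
  }
  gps <- params$participants
  n_p <- length(gps)
  design <- build_design(spec, seed = hash_mix(seed, "design"))
  tpc <- gps[[1L]]$trials_per_cell
  if (tpc %% spec$instances_per_type_per_list != 0L) {
    stop_config("trials_per_cell must be a multiple of instances_per_type_per_list (",
                spec$instances_per_type_per_list, ")")
  }
  lists_per_p <- tpc %/% spec$instances_per_type_per_list
  if (lists_per_p > spec$n_lists) {
    stop_config("trials_per_cell exceeds the trials available across all lists")
  }
  lagcols <- paste0("lag_", seq_len(spec$n_tones))
  rows <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    pid <- params$abilities$participant[p]
    use_lists <- ((p - 1L + seq_len(lists_per_p) - 1L) %% spec$n_lists) + 1L
    tr <- design[design$list %in% use_lists, , drop = FALSE]
    ord <- with_seed(hash_mix(seed, "order", p), sample.int(nrow(tr)))
    tr <- tr[ord, , drop = FALSE]
    constr <- tr$construction; acc <- tr$acceptable; ctrl <- tr$control_anomaly
    codes <- t(vapply(seq_len(nrow(tr)), function(i) {
      simulate_trial_lags(gps[[p]],
                          list(construction = constr[i], acceptable = acc[i],
                               control_anomaly = ctrl[i]),
                          spec, seed = hash_mix(seed, "trial", p, i))
    }, character(spec$n_tones)))
    colnames(codes) <- lagcols
    rows[[p]] <- cbind(
      data.frame(participant = pid, list = tr$list,
                 trial = seq_len(nrow(tr)), item = tr$item,
                 sentence_type = tr$sentence_type,
                 construction = tr$construction,
                 acceptable = tr$acceptable,
                 control_anomaly = tr$control_anomaly,
                 stringsAsFactors = FALSE),
      as.data.frame(codes, stringsAsFactors = FALSE)
    )
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  structure(list(trials = trials, abilities = params$abilities,
                 spec = spec, params = params),
            class = "sat_cohort")
}

#' @export
print.sat_cohort <- function(x, ...) {
  cat(sprintf("MR-SAT simulated cohort: %d participants, %d trials\n",
              nrow(x$abilities), nrow(x$trials)))
  invisible(x)
}

#' Render per-lag codes as a key-press event stream
#'
#' Emits `down`/`up` events so that during each tone window exactly the keys
#' implied by its code are held (both for `BOTH`, one for `YES`/`NO`, none
#' for `NONE`). The response window runs for `response_period` seconds from
#' the first tone; keys still held at window end are released there.
#' Round-trips with [parse_stream()].
#'
#' @param codes character vector of per-lag codes, one per tone.
#' @param spec a [design_spec()].
#' @param participant,trial identifiers copied into the stream.
#' @return data frame `participant`, `trial`, `time_s`, `key`, `action`.
#' @export
render_stream <- function(codes, spec, participant = "P01", trial = 1L) {
  stopifnot(inherits(spec, "sat_design"))
  if (length(codes) != spec$n_tones) {
    stop_data("expected ", spec$n_tones, " lag codes, got ", length(codes))
  }
  if (length(codes) > 0 && !all(codes %in% CODE_LEVELS)) {
    stop_data("invalid lag codes: ",
              paste(unique(setdiff(codes, CODE_LEVELS)), collapse = ", "))
  }
  tt <- lag_times(spec)
  keys_for <- function(code) switch(code,
    BOTH = c("YES", "NO"), YES = "YES", NO = "NO", NONE = character(0))
  ev_time <- numeric(0); ev_key <- character(0); ev_act <- character(0)
  held <- character(0)
  for (k in seq_along(codes)) {
    want <- keys_for(codes[k])
    for (key in setdiff(held, want)) {
      ev_time <- c(ev_time, tt[k]); ev_key <- c(ev_key, key); ev_act <- c(ev_act, "up")
    }
    for (key in setdiff(want, held)) {
      ev_time <- c(ev_time, tt[k]); ev_key <- c(ev_key, key); ev_act <- c(ev_act, "down")
    }
    held <- want
  }
  if (length(codes) > 0 && length(held) > 0) {
    t_end <- tt[1] + spec$response_period
    for (key in held) {
      ev_time <- c(ev_time, t_end); ev_key <- c(ev_key, key); ev_act <- c(ev_act, "up")
    }
  }
  data.frame(participant = rep(participant, length(ev_time)),
             trial = rep(trial, length(ev_time)),
             time_s = ev_time, key = ev_key, action = ev_act,
             stringsAsFactors = FALSE)
}
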